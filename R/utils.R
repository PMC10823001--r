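# internal helpers: conditions and seeded evaluation

stop_usage <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("wheelrun_usage_error", "error", "condition")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("wheelrun_validation_error", "error", "condition")))
}

#' Evaluate an expression with a local random seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state. All randomness in the package flows through this helper so
#' that no function mutates global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("`seed` must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# parse "HH:MM" or "HH:MM:SS" to seconds after midnight
clock_to_sec <- function(x) {
  p <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(p) < 2L || length(p) > 3L || anyNA(suppressWarnings(as.numeric(p))))
    stop_validation(sprintf("invalid clock time '%s' (expected HH:MM[:SS])", x))
  n <- as.numeric(p)
  n[1] * 3600 + n[2] * 60 + if (length(n) == 3L) n[3] else 0
}
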