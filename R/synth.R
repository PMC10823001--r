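#' Generative parameters for the circadian running simulator
#'
#' Describes a nocturnal, bouted wheel-running phenotype under a fixed
#' light/dark cycle. Running is an alternating-renewal bout process: bout
#' starts follow a Poisson process whose rate differs between the dark and
#' light phase so that an expected `dark_activity_fraction` of all
#' rotations fall in the dark phase; bout lengths are exponential; within a
#' bout, rotations follow a hard-core renewal process (minimum gap
#' `min_gap_ms`, a physical ceiling on running speed) with mean rate
#' `rot_per_min`. Days are logger sessions that start at lights-off, so
#' session time 0 to `photoperiod_h` hours is the dark phase.
#'
#' Within-night bout statistics are order-of-magnitude defaults for
#' laboratory mice (a few bouts per active hour, ~10-min bouts, 60--120
#' rotations/min while running), not fitted values; see the package
#' vignette for how they were chosen.
#'
#' @param n_days number of simulated sessions (default 13, a two-week
#'   acquisition study minus a dropped final day).
#' @param lights_off clock time of lights-off, `"HH:MM"` (default
#'   `"10:20"`, a reversed light cycle).
#' @param photoperiod_h hours of darkness per day (default 12).
#' @param dark_activity_fraction expected proportion of rotations in the
#'   dark phase, in [0, 1] (default 0.9; mice are strongly nocturnal
#'   runners).
#' @param bout_rate_per_h mean bout starts per dark-phase hour.
#' @param bout_duration_min mean bout length, minutes (exponential).
#' @param rot_per_min mean rotation rate within a bout.
#' @param ramp per-day multiplicative escalation of `rot_per_min`
#'   (models acquisition of running over days; 1 = none).
#' @param min_gap_ms hard minimum between successive rotations,
#'   milliseconds. Must exceed the decoder lockout for lossless detection;
#'   the default 150 ms corresponds to a top speed of ~9.6 km/h on the
#'   127 mm wheel.
#' @return object of class `behavior_params`.
#' @export
behavior_params <- function(n_days = 13L, lights_off = "10:20",
                            photoperiod_h = 12,
                            dark_activity_fraction = 0.9,
                            bout_rate_per_h = 1.2,
                            bout_duration_min = 10,
                            rot_per_min = 90,
                            ramp = 1,
                            min_gap_ms = 150) {
  if (dark_activity_fraction < 0 || dark_activity_fraction > 1)
    stop_validation("`dark_activity_fraction` must be in [0, 1]")
  rates <- c(bout_rate_per_h, bout_duration_min, rot_per_min, ramp)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_validation("rates and durations must be finite and >= 0")
  if (photoperiod_h <= 0 || photoperiod_h >= 24)
    stop_validation("`photoperiod_h` must be in (0, 24)")
  if (n_days < 1) stop_validation("`n_days` must be >= 1")
  clock_to_sec(lights_off) # validates format
  structure(list(n_days = as.integer(n_days), lights_off = lights_off,
                 photoperiod_h = photoperiod_h,
                 dark_activity_fraction = dark_activity_fraction,
                 bout_rate_per_h = bout_rate_per_h,
                 bout_duration_min = bout_duration_min,
                 rot_per_min = rot_per_min, ramp = ramp,
                 min_gap_ms = min_gap_ms),
            class = "behavior_params")
}

#' Contact-bounce model for emitted switch events
#'
#' With probability `p_bounce` a rotation's closure is followed by a burst
#' of spurious open/close edge pairs inside `burst_window_ms`. The default
#' 3 ms window is about a tenth of the 30 ms lockout, so a correctly
#' configured decoder suppresses bursts entirely.
#'
#' @param p_bounce probability a rotation bounces, in [0, 1].
#' @param burst_window_ms width of the burst after the closing edge, ms.
#' @param burst_pairs_mean mean number of spurious edge pairs per burst
#'   (at least one pair is emitted when a burst occurs).
#' @return object of class `bounce_params`.
#' @export
bounce_params <- function(p_bounce = 0, burst_window_ms = 3,
                          burst_pairs_mean = 2) {
  if (p_bounce < 0 || p_bounce > 1)
    stop_validation("`p_bounce` must be in [0, 1]")
  if (burst_window_ms <= 0) stop_validation("`burst_window_ms` must be > 0")
  structure(list(p_bounce = p_bounce, burst_window_ms = burst_window_ms,
                 burst_pairs_mean = burst_pairs_mean),
            class = "bounce_params")
}

#' Wheel-fault model
#'
#' `offline_intervals` models a broken or unplugged reed switch: during the
#' listed intervals the channel emits no edges at all (data are missing,
#' not zero). `drag_factor` models mechanical drag, e.g. waste build-up on
#' a low-profile wheel, as a multiplicative thinning of rotations.
#'
#' @param offline_intervals `data.frame` with columns `day`, `start_min`,
#'   `end_min` (minutes within session, half-open), or `NULL` for none.
#' @param drag_factor probability a rotation survives drag, in (0, 1].
#' @return object of class `fault_spec`.
#' @export
fault_spec <- function(offline_intervals = NULL, drag_factor = 1) {
  if (!is.null(offline_intervals)) {
    need <- c("day", "start_min", "end_min")
    if (!all(need %in% names(offline_intervals)))
      stop_validation("`offline_intervals` needs columns day, start_min, end_min")
    if (any(offline_intervals$start_min < 0) ||
        any(offline_intervals$end_min > 1440))
      stop_validation("offline intervals must lie within the 1440-min session")
  }
  if (drag_factor <= 0 || drag_factor > 1)
    stop_validation("`drag_factor` must be in (0, 1]")
  structure(list(offline_intervals = offline_intervals,
                 drag_factor = drag_factor),
            class = "fault_spec")
}

# rotation times (ms) for one bout via a hard-core renewal process
bout_rotations <- function(start_ms, end_ms, rot_per_min, min_gap_ms) {
  if (end_ms <= start_ms || rot_per_min <= 0) return(numeric(0))
  mean_gap <- 60000 / rot_per_min
  span <- end_ms - start_ms
  n_max <- ceiling(span / min(mean_gap, min_gap_ms)) + 10L
  gaps <- if (mean_gap > min_gap_ms) {
    min_gap_ms + stats::rexp(n_max, rate = 1 / (mean_gap - min_gap_ms))
  } else rep(min_gap_ms, n_max)
  t <- start_ms + cumsum(gaps)
  t[t < end_ms]
}

# one day's rotation times (ms since session start at lights-off)
simulate_day <- function(params, day_mult) {
  dark_ms <- params$photoperiod_h * 3.6e6
  day_ms <- 86400000
  f <- params$dark_activity_fraction
  bouts_per_day <- params$bout_rate_per_h * params$photoperiod_h
  phases <- list(dark = c(0, dark_ms, f), light = c(dark_ms, day_ms, 1 - f))
  times <- numeric(0)
  for (ph in phases) {
    lo <- ph[1]; hi <- ph[2]; share <- ph[3]
    if (share <= 0 || bouts_per_day <= 0) next
    n_b <- stats::rpois(1, share * bouts_per_day)
    if (n_b == 0) next
    starts <- stats::runif(n_b, lo, hi)
    durs <- stats::rexp(n_b, rate = 1 / params$bout_duration_min) * 60000
    ends <- pmin(starts + durs, hi) # bouts do not cross the phase boundary
    for (b in seq_len(n_b))
      times <- c(times, bout_rotations(starts[b], ends[b],
                                       params$rot_per_min * day_mult,
                                       params$min_gap_ms))
  }
  times <- sort(times)
  # overlapping bouts can interleave; enforce the hard-core gap globally so
  # the emitted truth is exactly recoverable through the decoder lockout
  if (length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= params$min_gap_ms) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  times
}

#' Simulate bouted wheel-running with known ground truth
#'
#' Draws per-day rotation times from the circadian bout model of
#' [behavior_params()] and tabulates ground-truth daily metrics with the
#' same wheel geometry and activity threshold the analysis layer uses, so
#' the decoded data path can be validated against exact truth.
#'
#' @param params a [behavior_params()].
#' @param seed integer seed; all randomness derives from it.
#' @param config an [analysis_config()] supplying wheel geometry and the
#'   active-minute threshold for the truth table.
#' @return object of class `wheel_sim`: list with `days` (per-day numeric
#'   vectors of rotation times, ms since session start at lights-off),
#'   `truth` (`data.frame`: `day`, `rotations`, `dark_rotations`,
#'   `distance_km`, `active_min`, `active_speed_kmh`), `params`, `config`.
#' @export
simulate_behavior <- function(params = behavior_params(), seed,
                              config = analysis_config()) {
  stopifnot(inherits(params, "behavior_params"))
  days <- with_seed(seed, {
    lapply(seq_len(params$n_days), function(d)
      simulate_day(params, params$ramp^(d - 1)))
  })
  dark_ms <- params$photoperiod_h * 3.6e6
  circ <- config$circumference_m
  thr <- config$active_threshold
  truth <- do.call(rbind, lapply(seq_len(params$n_days), function(d) {
    t <- days[[d]]
    counts <- tabulate(pmin(floor(t / 60000), 1439) + 1L, nbins = 1440L)
    act <- if (config$strict) counts > thr else counts >= thr
    a_min <- sum(act)
    a_dist <- sum(counts[act]) * circ / 1000
    data.frame(day = d, rotations = length(t),
               dark_rotations = sum(t < dark_ms),
               distance_km = length(t) * circ / 1000,
               active_min = a_min,
               active_speed_kmh = if (a_min > 0) a_dist / (a_min / 60) else NA_real_)
  }))
  structure(list(days = days, truth = truth, params = params,
                 config = config),
            class = "wheel_sim")
}

#' @export
print.wheel_sim <- function(x, ...) {
  cat(sprintf("wheel_sim: %d days, %d rotations (%.2f km total, %.0f%% dark)\n",
              x$params$n_days, sum(x$truth$rotations),
              sum(x$truth$distance_km),
              100 * sum(x$truth$dark_rotations) /
                max(1, sum(x$truth$rotations))))
  invisible(x)
}

# emit edges for one session's rotation times
emit_session <- function(times_ms, bounce, channel) {
  n <- length(times_ms)
  if (n == 0L)
    return(switch_events())
  gap_next <- c(diff(times_ms), 60000)
  dwell <- pmin(15, 0.4 * gap_next)
  t_all <- numeric(0); e_all <- character(0)
  burst <- stats::runif(n) < bounce$p_bounce
  for (i in seq_len(n)) {
    t0 <- times_ms[i]
    ts <- t0; es <- "CLOSED"
    if (burst[i]) {
      k <- 1L + stats::rpois(1, max(0, bounce$burst_pairs_mean - 1))
      w <- min(bounce$burst_window_ms, 0.8 * dwell[i])
      u <- sort(stats::runif(2L * k, 0.05 * w, w))
      ts <- c(ts, t0 + u)
      es <- c(es, rep(c("OPEN", "CLOSED"), k))
    }
    ts <- c(ts, t0 + dwell[i]); es <- c(es, "OPEN")
    t_all <- c(t_all, ts); e_all <- c(e_all, es)
  }
  keep <- t_all < 86400000
  switch_events(channel, t_all[keep], e_all[keep])
}

#' Emit a reed-switch edge stream for simulated rotations
#'
#' Converts true rotation times into the raw signal the logger would see:
#' each surviving rotation emits a CLOSED edge followed by an OPEN edge
#' (dwell shorter than the gap to the next rotation), optional bounce
#' bursts add spurious edge pairs inside the burst window, and faulted
#' intervals emit nothing at all.
#'
#' @param rotations a `wheel_sim` (per-day streams are produced) or a
#'   numeric vector of rotation times in ms for a single session.
#' @param bounce a [bounce_params()].
#' @param fault a [fault_spec()].
#' @param seed integer seed for bounce/drag randomness.
#' @param channel channel id stamped on the events (default 0).
#' @return for a `wheel_sim`, a list of per-day switch-event data frames;
#'   for a numeric vector, a single switch-event `data.frame`.
#' @export
emit_switch_events <- function(rotations, bounce = bounce_params(),
                               fault = fault_spec(), seed = 1L,
                               channel = 0L) {
  stopifnot(inherits(bounce, "bounce_params"), inherits(fault, "fault_spec"))
  one_day <- function(times, day) {
    if (fault$drag_factor < 1)
      times <- times[stats::runif(length(times)) < fault$drag_factor]
    oi <- fault$offline_intervals
    if (!is.null(oi)) {
      oi <- oi[oi$day == day, , drop = FALSE]
      for (i in seq_len(nrow(oi))) {
        lo <- oi$start_min[i] * 60000; hi <- oi$end_min[i] * 60000
        times <- times[times < lo | times >= hi]
      }
    }
    emit_session(times, bounce, channel)
  }
  if (inherits(rotations, "wheel_sim")) {
    with_seed(seed, lapply(seq_along(rotations$days), function(d)
      one_day(rotations$days[[d]], d)))
  } else {
    if (is.unsorted(rotations)) stop_validation("rotation times must be sorted")
    with_seed(seed, one_day(as.numeric(rotations), 1L))
  }
}

#' Simulate a cohort of animals across loggers
#'
#' Assigns animals to logger channels (at most 13 per logger), simulates
#' each animal's behaviour and emits its event streams. MouseIDs follow
#' the `"logger_channel"` convention used to identify animals on
#' multi-channel loggers.
#'
#' @param n_animals number of animals.
#' @param genotypes group labels cycled over animals.
#' @param params a single [behavior_params()] or a named list of them,
#'   one per genotype.
#' @param seed integer seed; per-animal sub-seeds are derived from it.
#' @param n_loggers number of loggers available.
#' @param config a [logger_config()].
#' @param bounce,fault passed to [emit_switch_events()].
#' @param sexes sex labels alternated over animals.
#' @return object of class `wheel_cohort`: list with `manifest`
#'   (`data.frame`: `mouse_id`, `logger`, `channel`, `sex`, `genotype`,
#'   `cohort`), `sims` (named list of `wheel_sim`), `events` (named list;
#'   per animal, a list of per-day event streams).
#' @export
make_cohort <- function(n_animals, genotypes = c("HS", "HD"),
                        params = behavior_params(), seed = 1L,
                        n_loggers = 3L, config = logger_config(),
                        bounce = bounce_params(), fault = fault_spec(),
                        sexes = c("F", "M")) {
  capacity <- n_loggers * config$n_channels
  if (n_animals > capacity)
    stop_validation(sprintf(
      "%d animals exceed capacity of %d loggers x %d channels = %d",
      n_animals, n_loggers, config$n_channels, capacity))
  if (n_animals < 1) stop_validation("`n_animals` must be >= 1")
  idx <- seq_len(n_animals)
  logger <- (idx - 1L) %/% config$n_channels + 1L
  channel <- (idx - 1L) %% config$n_channels
  geno <- rep_len(genotypes, n_animals)
  sex <- rep_len(sexes, n_animals)
  manifest <- data.frame(
    mouse_id = paste(logger, channel, sep = "_"),
    logger = logger, channel = channel, sex = sex, genotype = geno,
    cohort = 1L, stringsAsFactors = FALSE)
  get_params <- function(g) {
    if (inherits(params, "behavior_params")) params
    else if (!is.null(params[[g]])) params[[g]]
    else stop_validation(sprintf("no behavior_params for genotype '%s'", g))
  }
  sims <- vector("list", n_animals)
  events <- vector("list", n_animals)
  for (i in idx) {
    sub_seed <- (as.integer(seed) + i * 1009L) %% .Machine$integer.max
    sims[[i]] <- simulate_behavior(get_params(geno[i]), seed = sub_seed)
    events[[i]] <- emit_switch_events(sims[[i]], bounce = bounce,
                                      fault = fault,
                                      seed = sub_seed + 1L,
                                      channel = channel[i])
  }
  names(sims) <- names(events) <- manifest$mouse_id
  structure(list(manifest = manifest, sims = sims, events = events,
                 logger_config = config),
            class = "wheel_cohort")
}

#' @export
print.wheel_cohort <- function(x, ...) {
  cat(sprintf("wheel_cohort: %d animals on %d logger(s), %d days\n",
              nrow(x$manifest), length(unique(x$manifest$logger)),
              x$sims[[1]]$params$n_days))
  print(table(x$manifest$genotype, x$manifest$sex))
  invisible(x)
}
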