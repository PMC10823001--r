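#' Logger configuration
#'
#' Describes one data logger: how many wheel channels it multiplexes, the
#' debounce lockout, and the summary bin width. A single microcontroller
#' logger polls up to 13 reed switches; each magnet pass closes the switch
#' once per wheel rotation.
#'
#' @param n_channels number of wheel channels on the logger (1--13).
#' @param lockout_ms debounce lockout in milliseconds: closures within this
#'   time of the previously *detected* rotation are treated as contact
#'   bounce and ignored. Default 30 ms, roughly 10x the duration of the
#'   bounce signal of the reed switches used.
#' @param bin_s width of the summary bin in seconds (default 60: the logger
#'   records one row per channel per minute).
#' @return an object of class `logger_config`.
#' @export
logger_config <- function(n_channels = 13L, lockout_ms = 30, bin_s = 60L) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L || n_channels > 13L)
    stop_validation("`n_channels` must be an integer between 1 and 13")
  if (!is.numeric(lockout_ms) || lockout_ms <= 0)
    stop_validation("`lockout_ms` must be > 0")
  if (!is.numeric(bin_s) || bin_s <= 0)
    stop_validation("`bin_s` must be > 0")
  structure(list(n_channels = n_channels, lockout_ms = lockout_ms,
                 bin_s = as.numeric(bin_s)),
            class = "logger_config")
}

#' Construct a switch-event stream
#'
#' A switch event is one edge of a reed switch: the channel it occurred on,
#' its time in milliseconds since logger reset, and whether the switch
#' opened or closed. Times may be fractional; events on a channel must be
#' non-decreasing in time. Non-alternating duplicate edges are tolerated
#' (real switches glitch): they are counted as events but only the first
#' changes the tracked switch state.
#'
#' @param channel integer channel ids.
#' @param t_ms event times, milliseconds since logger reset (>= 0).
#' @param edge `"OPEN"` or `"CLOSED"` per event.
#' @return a `data.frame` with columns `channel`, `t_ms`, `edge`.
#' @export
switch_events <- function(channel = integer(), t_ms = numeric(),
                          edge = character()) {
  if (length(channel) == 1L && length(t_ms) != 1L)
    channel <- rep_len(channel, length(t_ms))
  if (length(unique(c(length(channel), length(t_ms), length(edge)))) != 1L)
    stop_validation("`channel`, `t_ms` and `edge` must have equal length")
  edge <- toupper(as.character(edge))
  if (!all(edge %in% c("OPEN", "CLOSED")))
    stop_validation("`edge` values must be 'OPEN' or 'CLOSED'")
  if (any(t_ms < 0)) stop_validation("`t_ms` must be >= 0")
  data.frame(channel = as.integer(channel), t_ms = as.numeric(t_ms),
             edge = edge, stringsAsFactors = FALSE)
}

check_sorted <- function(events) {
  for (ch in unique(events$channel)) {
    t <- events$t_ms[events$channel == ch]
    if (is.unsorted(t)) # non-decreasing required
      stop_validation(sprintf(
        "events on channel %d are not sorted by t_ms", ch))
  }
  invisible(events)
}

# TRUE for edges that are OPEN->CLOSED transitions of the tracked state.
# State before the first edge is the opposite of the first edge, so a
# leading CLOSED edge is always a transition. Duplicate edges (same value
# as the current state) do not change state and are not transitions.
closed_transitions <- function(edge) {
  n <- length(edge)
  if (n == 0L) return(logical(0))
  prev <- c(if (edge[1] == "CLOSED") "OPEN" else "CLOSED", edge[-n])
  edge == "CLOSED" & prev == "OPEN"
}

#' Detect wheel rotations from a switch-event stream
#'
#' Applies the logger's debouncing rule: every OPEN-to-CLOSED transition is
#' a candidate rotation, but a candidate within `lockout_ms` of the
#' previously *detected* rotation on the same channel is discarded as
#' contact bounce. The lockout is non-retriggerable: ignored edges do not
#' reset the timer, so a candidate exactly `lockout_ms` (or more) after the
#' last detected rotation is accepted. The first closure on a channel
#' always detects.
#'
#' @param events a switch-event `data.frame` (see [switch_events()]),
#'   sorted by `t_ms` within each channel.
#' @param lockout_ms debounce lockout, milliseconds.
#' @return `data.frame` with columns `channel`, `t_ms`: one row per
#'   detected rotation, in time order within channel.
#' @examples
#' ev <- switch_events(0, c(0, 5, 10, 15, 40, 45, 80),
#'                     c("CLOSED","OPEN","CLOSED","OPEN","CLOSED","OPEN","CLOSED"))
#' detect_rotations(ev, lockout_ms = 30)  # 0, 40, 80; the 10 ms edge is bounce
#' @export
detect_rotations <- function(events, lockout_ms = 30) {
  if (!is.numeric(lockout_ms) || lockout_ms <= 0)
    stop_validation("`lockout_ms` must be > 0")
  if (nrow(events) == 0L)
    return(data.frame(channel = integer(), t_ms = numeric()))
  check_sorted(events)
  out <- lapply(split(events, events$channel), function(ev) {
    cand <- ev$t_ms[closed_transitions(ev$edge)]
    if (length(cand) == 0L)
      return(data.frame(channel = integer(), t_ms = numeric()))
    keep <- logical(length(cand))
    last <- -Inf
    for (i in seq_along(cand)) {
      if (cand[i] - last >= lockout_ms) {
        keep[i] <- TRUE
        last <- cand[i]
      }
    }
    data.frame(channel = ev$channel[1], t_ms = cand[keep])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# piecewise-constant switch state: data.frame(start, end, state) covering
# [0, horizon_ms). Initial state is the opposite of the first edge.
state_intervals <- function(edge, t_ms, horizon_ms) {
  if (length(edge) == 0L)
    return(data.frame(start = 0, end = horizon_ms, state = "OPEN"))
  init <- if (edge[1] == "CLOSED") "OPEN" else "CLOSED"
  prev <- c(init, edge[-length(edge)])
  chg <- edge != prev
  starts <- c(0, t_ms[chg])
  states <- c(init, edge[chg])
  data.frame(start = starts, end = c(starts[-1], horizon_ms), state = states,
             stringsAsFactors = FALSE)
}

#' Summarise events and rotations into per-minute logger records
#'
#' Reproduces the logger's one-row-per-minute record: counts of open and
#' close events, milliseconds the switch spent open and closed, and the
#' number of detected rotations, per channel. Minute bins are
#' left-closed/right-open, `[k*60000, (k+1)*60000)` ms, anchored at logger
#' reset; switch state is carried across bin boundaries so open + closed
#' dwell equals the bin width for every complete minute.
#'
#' @param events switch-event `data.frame` for the session.
#' @param rotations detected rotations, as returned by [detect_rotations()].
#' @param config a [logger_config()].
#' @param n_minutes number of minutes in the session; defaults to the
#'   smallest horizon covering all events and rotations (minimum 1).
#' @return `data.frame` with one row per channel per minute: `channel`,
#'   `minute`, `open_events`, `close_events`, `open_dur_ms`,
#'   `closed_dur_ms`, `rotations`.
#' @export
summarize_minutes <- function(events, rotations, config = logger_config(),
                              n_minutes = NULL) {
  bin_ms <- config$bin_s * 1000
  tmax <- suppressWarnings(max(c(events$t_ms, rotations$t_ms, 0)))
  if (is.null(n_minutes)) n_minutes <- max(1L, ceiling((tmax + 1e-9) / bin_ms))
  n_minutes <- as.integer(n_minutes)
  if (tmax >= n_minutes * bin_ms)
    stop_validation("events or rotations fall beyond the session horizon")
  channels <- sort(unique(c(events$channel, rotations$channel)))
  if (length(channels) == 0L) channels <- 0L
  out <- lapply(channels, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    rot <- rotations[rotations$channel == ch, , drop = FALSE]
    minute_of <- function(t) pmin(floor(t / bin_ms), n_minutes - 1L)
    cnt <- function(t) tabulate(minute_of(t) + 1L, nbins = n_minutes)
    open_events <- cnt(ev$t_ms[ev$edge == "OPEN"])
    close_events <- cnt(ev$t_ms[ev$edge == "CLOSED"])
    rots <- cnt(rot$t_ms)
    closed_dur <- numeric(n_minutes)
    iv <- state_intervals(ev$edge, ev$t_ms, n_minutes * bin_ms)
    iv <- iv[iv$state == "CLOSED" & iv$end > iv$start, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      a <- iv$start[i]; b <- iv$end[i]
      ks <- floor(a / bin_ms):floor((b - 1e-9) / bin_ms)
      closed_dur[ks + 1L] <- closed_dur[ks + 1L] +
        (pmin(b, (ks + 1) * bin_ms) - pmax(a, ks * bin_ms))
    }
    data.frame(channel = ch, minute = seq_len(n_minutes) - 1L,
               open_events = open_events, close_events = close_events,
               open_dur_ms = bin_ms - closed_dur, closed_dur_ms = closed_dur,
               rotations = rots)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Decode a multi-channel event stream into per-minute records
#'
#' Demultiplexes a raw multi-channel switch-event stream and applies
#' [detect_rotations()] and [summarize_minutes()] independently per
#' channel, producing the logger's minute records for every configured
#' channel (channels with no events yield all-zero records).
#'
#' @param events multi-channel switch-event `data.frame`.
#' @param config a [logger_config()]; event channel ids must be
#'   `< n_channels`.
#' @param n_minutes session length in minutes (default: cover all events).
#' @return `data.frame` of minute records for channels
#'   `0:(n_channels - 1)`, as in [summarize_minutes()].
#' @export
decode_stream <- function(events, config = logger_config(), n_minutes = NULL) {
  if (nrow(events) > 0 && any(events$channel >= config$n_channels))
    stop_validation(sprintf(
      "event channel id >= n_channels (%d)", config$n_channels))
  if (nrow(events) > 0 && any(events$channel < 0))
    stop_validation("negative channel id")
  check_sorted(events)
  bin_ms <- config$bin_s * 1000
  if (is.null(n_minutes)) {
    tmax <- suppressWarnings(max(c(events$t_ms, 0)))
    n_minutes <- max(1L, ceiling((tmax + 1e-9) / bin_ms))
  }
  rot <- detect_rotations(events, config$lockout_ms)
  out <- lapply(seq_len(config$n_channels) - 1L, function(ch) {
    summarize_minutes(events[events$channel == ch, , drop = FALSE],
                      rot[rot$channel == ch, , drop = FALSE],
                      config, n_minutes = n_minutes)
  })
  recs <- do.call(rbind, lapply(seq_along(out), function(i) {
    r <- out[[i]]
    r$channel <- i - 1L
    r
  }))
  rownames(recs) <- NULL
  recs
}

#' Maximum wheel speed recordable under a debounce lockout
#'
#' The lockout imposes a ceiling on detectable rotation rate: one rotation
#' per `lockout_ms`. At wheel circumference \eqn{C} metres the ceiling is
#' \eqn{C / (lockout/1000) \times 3.6} km/h. For the default 127 mm wheel
#' (circumference \eqn{\pi \times 0.127} m) and 30 ms lockout this is about
#' 47.9 km/h, far above murine sprinting speed.
#'
#' @param circumference_m wheel circumference, metres (> 0).
#' @param lockout_ms debounce lockout, milliseconds (> 0).
#' @return speed in km/h.
#' @export
max_recordable_speed <- function(circumference_m = pi * 0.127,
                                 lockout_ms = 30) {
  if (!is.numeric(circumference_m) || any(circumference_m <= 0))
    stop_validation("`circumference_m` must be > 0")
  if (!is.numeric(lockout_ms) || any(lockout_ms <= 0))
    stop_validation("`lockout_ms` must be > 0")
  circumference_m / (lockout_ms / 1000) * 3.6
}
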