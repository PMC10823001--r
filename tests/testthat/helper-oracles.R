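# Independent oracles and small fixture builders used across tests.

# Naive O(n^2) replay of the debounce rule for one channel, written
# directly from first principles: walk the edges tracking switch state;
# every OPEN->CLOSED transition is a candidate rotation, accepted iff no
# previously accepted rotation lies within `lockout` ms before it.
oracle_detect <- function(t_ms, edge, lockout) {
  state <- if (length(edge) && edge[1] == "CLOSED") "OPEN" else "CLOSED"
  detected <- numeric(0)
  for (i in seq_along(edge)) {
    if (edge[i] == "CLOSED" && state == "OPEN") {
      hit <- any(t_ms[i] - detected >= 0 & t_ms[i] - detected < lockout)
      if (!hit) detected <- c(detected, t_ms[i])
    }
    if (edge[i] != state) state <- edge[i]
  }
  detected
}

# random single-channel edge stream; allows duplicate (glitchy) edges
random_stream <- function(n_edges, span_ms = 2000, channel = 0L) {
  t <- sort(runif(n_edges, 0, span_ms))
  e <- sample(c("OPEN", "CLOSED"), n_edges, replace = TRUE)
  switch_events(channel, t, e)
}

# clean alternating stream: one CLOSED/OPEN pair per rotation time
clean_stream <- function(times_ms, dwell = 10, channel = 0L) {
  n <- length(times_ms)
  if (n == 0) return(switch_events())
  switch_events(channel,
                as.vector(rbind(times_ms, times_ms + dwell)),
                rep(c("CLOSED", "OPEN"), n))
}

# stitched-style minute series from a vector (or day-list) of counts
make_series <- function(counts, mouse_id = "1_0",
                        start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                        day_len = 1440L) {
  if (!is.list(counts)) counts <- list(counts)
  do.call(rbind, lapply(seq_along(counts), function(d) {
    rot <- counts[[d]]
    minute <- seq_along(rot) - 1L
    data.frame(mouse_id = mouse_id,
               day_label = as.Date(start) + d - 1L,
               day_index = d, minute = minute,
               timestamp = start + (d - 1L) * day_len * 60 + minute * 60,
               rotations = rot)
  }))
}
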