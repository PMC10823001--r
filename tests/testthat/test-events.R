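test_that("lockout detector keeps real closures and discards bounce", {
  # closures at 0, 10, 40, 80 ms with OPEN edges between: the 10 ms edge
  # falls inside the 30 ms lockout of the detection at 0
  ev <- switch_events(0, c(0, 5, 10, 15, 40, 45, 80),
                      c("CLOSED", "OPEN", "CLOSED", "OPEN", "CLOSED",
                        "OPEN", "CLOSED"))
  expect_equal(detect_rotations(ev, 30)$t_ms, c(0, 40, 80))

  # non-retriggerable: the ignored 20 ms closure does not reset the timer,
  # so 40 ms (40 ms after the last *detected* rotation) is accepted
  ev2 <- switch_events(0, c(0, 5, 20, 25, 40),
                       c("CLOSED", "OPEN", "CLOSED", "OPEN", "CLOSED"))
  expect_equal(detect_rotations(ev2, 30)$t_ms, c(0, 40))

  # a closure exactly lockout_ms after the last detection is accepted
  ev3 <- clean_stream(c(0, 30))
  expect_equal(detect_rotations(ev3, 30)$t_ms, c(0, 30))

  expect_equal(nrow(detect_rotations(switch_events(), 30)), 0L)
})

test_that("only open-to-closed transitions register; duplicates tolerated", {
  # duplicate CLOSED edges: counted as events but only the first changes
  # state, so the second is not a transition and cannot detect
  ev <- switch_events(0, c(0, 100), c("CLOSED", "CLOSED"))
  expect_equal(detect_rotations(ev, 30)$t_ms, 0)
  rec <- summarize_minutes(ev, detect_rotations(ev, 30), logger_config())
  expect_equal(rec$close_events, 2L)
  expect_equal(rec$rotations, 1L)

  # OPEN edges never register rotations
  ev2 <- switch_events(0, c(0, 50), c("OPEN", "OPEN"))
  expect_equal(nrow(detect_rotations(ev2, 30)), 0L)
})

test_that("unsorted input is rejected", {
  ev <- switch_events(c(0, 0), c(100, 50), c("CLOSED", "OPEN"))
  expect_error(detect_rotations(ev, 30), "sorted")
})

test_that("streaming detector equals the naive replay oracle", {
  set.seed(101)
  for (rep in 1:200) {
    ev <- random_stream(sample(0:40, 1))
    lock <- sample(c(5, 30, 100), 1)
    got <- detect_rotations(ev, lock)$t_ms
    expect_equal(got, oracle_detect(ev$t_ms, ev$edge, lock))
  }
})

test_that("increasing the lockout never increases the rotation count", {
  set.seed(202)
  for (rep in 1:50) {
    ev <- random_stream(sample(5:50, 1))
    counts <- vapply(c(1, 10, 30, 100, 500),
                     function(l) nrow(detect_rotations(ev, l)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("minute records count, bin and conserve correctly", {
  cfg <- logger_config()
  # five rotations in minute 0, then silence
  ev <- clean_stream(c(0, 200, 400, 600, 800) * 60) # 0..48 s
  rot <- detect_rotations(ev, cfg$lockout_ms)
  rec <- summarize_minutes(ev, rot, cfg, n_minutes = 3)
  expect_equal(rec$rotations, c(5L, 0L, 0L))
  expect_equal(sum(rec$rotations), nrow(rot))

  # half-open bins: a rotation at 59,999.5 ms belongs to minute 0
  ev2 <- clean_stream(59999.5)
  rec2 <- summarize_minutes(ev2, detect_rotations(ev2, 30), cfg,
                            n_minutes = 2)
  expect_equal(rec2$rotations, c(1L, 0L))

  # switch held closed across a full minute with no edges inside it
  ev3 <- switch_events(0, 0, "CLOSED")
  rec3 <- summarize_minutes(ev3, detect_rotations(ev3, 30), cfg,
                            n_minutes = 2)
  expect_equal(rec3$open_events[2], 0L)
  expect_equal(rec3$close_events[2], 0L)
  expect_equal(rec3$closed_dur_ms[2], 60000)
})

test_that("dwell is complete and rotations are conserved on random streams", {
  set.seed(303)
  for (rep in 1:25) {
    ev <- random_stream(sample(1:60, 1), span_ms = 150000)
    rot <- detect_rotations(ev, 30)
    rec <- summarize_minutes(ev, rot, logger_config())
    expect_equal(sum(rec$rotations), nrow(rot))
    expect_true(all(abs(rec$open_dur_ms + rec$closed_dur_ms - 60000) < 1e-6))
    expect_true(all(rec$rotations <= rec$close_events))
  }
})

test_that("with all gaps above the lockout, rotations equal close events", {
  times <- cumsum(runif(200, 50, 500)) # every gap > 30 ms
  ev <- clean_stream(times)
  rec <- summarize_minutes(ev, detect_rotations(ev, 30), logger_config())
  expect_equal(rec$rotations, rec$close_events)
})

test_that("decode_stream demultiplexes channels independently", {
  times <- cumsum(runif(50, 50, 800))
  ev <- rbind(clean_stream(times, channel = 0L),
              clean_stream(times, channel = 1L))
  ev <- ev[order(ev$channel, ev$t_ms), ]
  cfg <- logger_config(n_channels = 2)
  rec <- decode_stream(ev, cfg)
  r0 <- rec[rec$channel == 0, -1]
  r1 <- rec[rec$channel == 1, -1]
  rownames(r0) <- rownames(r1) <- NULL
  expect_equal(r0, r1)

  # 13 configured channels, one active: the other 12 are all-zero
  rec13 <- decode_stream(clean_stream(times, channel = 4L),
                         logger_config(n_channels = 13))
  idle <- rec13[rec13$channel != 4, ]
  expect_true(all(idle$rotations == 0 & idle$close_events == 0))
  expect_equal(length(unique(rec13$channel)), 13L)

  # random multi-channel stream equals per-channel brute force
  set.seed(404)
  ev3 <- do.call(rbind, lapply(0:2, function(ch)
    random_stream(30, span_ms = 180000, channel = ch)))
  rec3 <- decode_stream(ev3, logger_config(n_channels = 3))
  for (ch in 0:2) {
    sub <- ev3[ev3$channel == ch, ]
    n_oracle <- length(oracle_detect(sub$t_ms, sub$edge, 30))
    expect_equal(sum(rec3$rotations[rec3$channel == ch]), n_oracle)
  }

  expect_error(decode_stream(clean_stream(times, channel = 5L),
                             logger_config(n_channels = 3)),
               "n_channels")
})

test_that("max recordable speed follows the closed form", {
  # 127 mm wheel, 30 ms lockout: pi * 0.127 / 0.030 * 3.6
  expect_equal(max_recordable_speed(pi * 0.127, 30),
               pi * 0.127 / 0.030 * 3.6)
  expect_equal(max_recordable_speed(pi * 0.127, 30), 47.878, tolerance = 1e-4)
  # an effective circumference of 0.458 m puts the ceiling at ~55 km/h
  expect_equal(max_recordable_speed(0.458, 30), 54.96, tolerance = 1e-4)
  # speed ceiling vanishes as the lockout grows
  expect_lt(max_recordable_speed(pi * 0.127, 1e9), 1e-5)
  expect_error(max_recordable_speed(0, 30), "circumference")
  expect_error(max_recordable_speed(1, -1), "lockout")
})

test_that("logger_config validates its ranges", {
  expect_error(logger_config(n_channels = 14), "13")
  expect_error(logger_config(lockout_ms = 0), "lockout")
  expect_s3_class(logger_config(1, 30), "logger_config")
})
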