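test_that("the derived activity threshold is the nonzero lower quartile", {
  expect_equal(derive_active_threshold(c(17, 17, 17, 17)), 17L)
  # nearest-rank Q1 of {10,20,30,40} is the ceiling(4/4)=1st order statistic
  expect_equal(derive_active_threshold(c(10, 20, 30, 40)), 10L)
  # zeros are excluded before the quartile
  expect_equal(derive_active_threshold(c(0, 0, 0, 10, 20, 30, 40)), 10L)
  expect_error(derive_active_threshold(c(0, 0, 0)), "nonzero")
  # brute-force oracle on a larger pool
  set.seed(8)
  x <- rpois(500, 40)
  x <- x[x > 0]
  expect_equal(derive_active_threshold(x),
               as.integer(round(sort(x)[ceiling(length(x) / 4)])))
  expect_equal(derive_active_threshold(x, method = "type7"),
               as.integer(round(quantile(x, 0.25, names = FALSE))))
})

test_that("active-minute classification respects strict boundaries", {
  expect_true(classify_active(31, 30, strict = TRUE))
  expect_false(classify_active(30, 30, strict = TRUE))
  expect_true(classify_active(30, 30, strict = FALSE))
  # chronic-style threshold: a minute with 18 rotations beats 17
  expect_true(classify_active(18, 17, strict = TRUE))
  expect_false(classify_active(17, 17, strict = TRUE))
})

test_that("daily summaries compute distance and active-only speed", {
  cfg <- analysis_config()
  circ <- pi * 0.127
  # 1000 rotations spread thinly: distance counts every minute
  counts <- c(rep(10, 100), rep(0, 1340))
  s <- daily_summary(make_series(counts), cfg)
  expect_equal(s$distance_km, 1000 * circ / 1000)
  expect_equal(s$distance_km, 0.3990, tolerance = 1e-3)
  expect_equal(s$active_min, 0L) # 10 <= 30: nothing active
  expect_true(is.na(s$active_speed_kmh))

  # one active minute of 60 rotations
  counts2 <- c(60, rep(0, 1439))
  s2 <- daily_summary(make_series(counts2), cfg)
  expect_equal(s2$active_min, 1L)
  expect_equal(s2$active_speed_kmh, (60 * circ / 1000) / (1 / 60))
  expect_equal(s2$active_speed_kmh, 1.436, tolerance = 1e-3)

  # all-zero day
  s3 <- daily_summary(make_series(rep(0, 1440)), cfg)
  expect_equal(s3$distance_km, 0)
  expect_equal(s3$active_min, 0L)

  # speed uses only active minutes: inactive rotations add distance only
  counts4 <- c(60, 10, rep(0, 1438))
  s4 <- daily_summary(make_series(counts4), cfg)
  expect_equal(s4$active_speed_kmh, s2$active_speed_kmh)
  expect_gt(s4$distance_km, s2$distance_km)
})

test_that("scaling the wheel scales distance and speed, not activity", {
  counts <- c(rep(40, 30), rep(0, 1410))
  s1 <- daily_summary(make_series(counts), analysis_config())
  s2 <- daily_summary(make_series(counts),
                      analysis_config(circumference_m = 2 * pi * 0.127))
  expect_equal(s2$distance_km, 2 * s1$distance_km)
  expect_equal(s2$active_speed_kmh, 2 * s1$active_speed_kmh)
  expect_equal(s2$active_min, s1$active_min)
})

test_that("quartile threshold mode matches an explicit fixed threshold", {
  counts <- list(c(rep(25, 200), rep(80, 600), rep(0, 640)))
  series <- make_series(counts)
  thr <- derive_active_threshold(series$rotations)
  s_q <- daily_summary(series, analysis_config(threshold_mode = "quartile"))
  s_f <- daily_summary(series, analysis_config(active_threshold = thr))
  expect_equal(attr(s_q, "active_threshold"), thr)
  expect_equal(s_q$active_min, s_f$active_min)
  expect_equal(s_q$active_speed_kmh, s_f$active_speed_kmh)
})

test_that("exclusion rules flag but keep animal-days", {
  mk_day <- function(active_minutes, rot = 60) {
    c(rep(rot, active_minutes), rep(0, 1440 - active_minutes))
  }
  series <- make_series(list(mk_day(19), mk_day(20), mk_day(25)))
  s <- apply_exclusions(daily_summary(series), analysis_config())
  expect_equal(nrow(s), 3L) # rows retained, only flagged
  expect_equal(s$exclusion_reason[s$day_index == 1], "TOO_FEW_ACTIVE_MIN")
  expect_false(s$excluded[s$day_index == 2])
  expect_false(s$excluded[s$day_index == 3])

  # an implausible speed day among ordinary ~1.4 km/h days is flagged
  days <- c(replicate(5, mk_day(60, 60), simplify = FALSE),
            list(mk_day(60, 1300))) # ~31 km/h
  s2 <- apply_exclusions(daily_summary(make_series(days)), analysis_config())
  expect_equal(s2$exclusion_reason[s2$day_index == 6], "SPEED_OUTLIER")
  expect_true(all(s2$exclusion_reason[s2$day_index < 6] == "NONE"))

  # the robust per-animal rule catches spikes under the absolute cap
  days3 <- c(list(mk_day(60, 55), mk_day(60, 62), mk_day(60, 58),
                  mk_day(60, 60), mk_day(60, 350))) # ~8.4 km/h vs ~1.4
  s3 <- apply_exclusions(daily_summary(make_series(days3)),
                         analysis_config(speed_cap_kmh = 100))
  expect_equal(s3$exclusion_reason[s3$day_index == 5], "SPEED_OUTLIER")
})

test_that("weekly group summaries use the animal as the unit", {
  mk_day <- function(rot) c(rep(rot, 40), rep(0, 1400))
  circ <- pi * 0.127
  # two animals with constant daily distances of 1 and 2 km
  r1 <- round(1000 / circ / 40) # per-minute rotations for ~1 km/day
  r2 <- round(2000 / circ / 40)
  series <- rbind(make_series(replicate(7, mk_day(r1), simplify = FALSE),
                              mouse_id = "1_0"),
                  make_series(replicate(7, mk_day(r2), simplify = FALSE),
                              mouse_id = "1_1"))
  manifest <- data.frame(mouse_id = c("1_0", "1_1"), sex = "F",
                         genotype = "HS")
  w <- weekly_group_summary(daily_summary(series), manifest)
  wd <- w[w$metric == "distance_km", ]
  d1 <- 40 * r1 * circ / 1000
  d2 <- 40 * r2 * circ / 1000
  expect_equal(wd$mean, (d1 + d2) / 2)
  expect_equal(wd$sem, abs(d2 - d1) / 2) # SD/sqrt(2) of two points
  expect_equal(wd$n, 2L)

  # n = 1: SEM is reported absent
  w1 <- weekly_group_summary(daily_summary(series[series$mouse_id == "1_0", ]),
                             manifest[1, ])
  expect_true(all(is.na(w1$sem)))
  expect_true(all(w1$n == 1L))

  # an excluded day leaves the weekly mean's denominator
  days <- c(replicate(6, mk_day(r1), simplify = FALSE), list(mk_day(0)))
  s_ex <- apply_exclusions(daily_summary(make_series(days, mouse_id = "1_0")),
                           analysis_config())
  expect_true(s_ex$excluded[7])
  w_ex <- weekly_group_summary(s_ex, manifest[1, ])
  expect_equal(w_ex$mean[w_ex$metric == "distance_km"], d1) # not 6/7 of it

  # 13 sessions split into a 7-day week and a 6-day week
  days13 <- replicate(13, mk_day(r1), simplify = FALSE)
  w13 <- weekly_group_summary(daily_summary(make_series(days13,
                                                        mouse_id = "1_0")),
                              manifest[1, ])
  expect_equal(sort(unique(w13$week)), c(1L, 2L))
})

test_that("hourly profiles average distance per clock hour", {
  circ <- pi * 0.127
  # uniform running, 10 rotations every minute of 2 days
  series <- make_series(list(rep(10, 1440), rep(10, 1440)))
  manifest <- data.frame(mouse_id = "1_0", genotype = "HS")
  hp <- hourly_profile(series, manifest = manifest)
  expect_equal(nrow(hp), 24L)
  daily_km <- 1440 * 10 * circ / 1000
  expect_equal(hp$mean_kmh, rep(daily_km / 24, 24))

  # changing lights_off relabels zt/dark, never the values
  hp2 <- hourly_profile(series, lights_off = "12:20", manifest = manifest)
  expect_equal(hp2$mean_kmh, hp$mean_kmh)
  expect_false(identical(hp2$zt_hour, hp$zt_hour))
  # lights-off hour maps to ZT12
  expect_equal(hp$zt_hour[hp$hour == 10], 12)

  # running confined to the first session hour lands in that clock hour
  one_hr <- c(rep(30, 60), rep(0, 1380))
  s_oh <- make_series(list(one_hr),
                      start = as.POSIXct("2024-01-01 05:00:00", tz = "UTC"))
  hp3 <- hourly_profile(s_oh, manifest = manifest)
  expect_equal(sum(hp3$mean_kmh > 0), 1L)
  expect_equal(hp3$hour[hp3$mean_kmh > 0], 5L)
})

test_that("animals partition into High, Average and Low runner quartiles", {
  totals <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6, g = 7, h = 8)
  q <- quartile_partition(totals)
  expect_equal(sum(q$tier == "High"), 2L)
  expect_equal(sum(q$tier == "Low"), 2L)
  expect_equal(sum(q$tier == "Average"), 4L)
  expect_equal(q$tier[q$mouse_id %in% c("g", "h")], rep("High", 2))
  expect_equal(q$tier[q$mouse_id %in% c("a", "b")], rep("Low", 2))

  # all-equal totals: stable tie-break by input order
  q_tie <- quartile_partition(setNames(rep(1, 8), letters[1:8]))
  expect_equal(q_tie$tier[1:2], rep("Low", 2))
  expect_equal(q_tie$tier[7:8], rep("High", 2))

  expect_warning(q3 <- quartile_partition(c(a = 1, b = 2, c = 3)),
                 "degenerate")
  expect_true(all(q3$tier == "Average"))
})

test_that("density summaries exclude zero minutes by default", {
  d <- density_data(c(0, 0, 5, 10))
  expect_equal(d$values, c(5, 10))
  expect_equal(d$mean, 7.5)
  expect_equal(d$median, 7.5)

  d0 <- density_data(c(0, 0, 0))
  expect_length(d0$values, 0L)
  expect_true(is.na(d0$mean) && is.na(d0$median))

  expect_equal(density_data(c(0, 0, 5, 10), exclude_zeros = FALSE)$mean, 3.75)
})

test_that("zero-minute fraction counts rest minutes", {
  expect_equal(zero_minute_fraction(rep(0, 100)), 1)
  expect_equal(zero_minute_fraction(rep(c(1, 0), 50)), 0.5)
  expect_error(zero_minute_fraction(numeric(0)), "empty")
})
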