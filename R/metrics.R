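#' Analysis configuration
#'
#' Collects the tunable constants of the wheel-running analysis: wheel
#' geometry, the active-minute threshold rule, the daily inclusion rule,
#' and speed-outlier handling.
#'
#' The active-minute threshold is either fixed (default 30: a minute
#' counts as running only when rotations exceed 30, the convention for a
#' short acquisition study) or derived as the lower quartile of nonzero
#' per-minute rotation counts pooled over the cohort
#' ([derive_active_threshold()]), which gives 17 on typical chronic data.
#' The comparison is strict (`>`) by default; set `strict = FALSE` for
#' `>=`.
#'
#' @param wheel_diameter_m wheel diameter in metres (default 0.127, a
#'   127 mm low-profile wheel).
#' @param circumference_m effective rolling circumference; defaults to
#'   `pi * wheel_diameter_m` but may be overridden (e.g. calibrated).
#' @param active_threshold rotations/minute above which a minute is
#'   "active" (default 30).
#' @param threshold_mode `"fixed"` or `"quartile"` (derive the threshold
#'   from the data with [derive_active_threshold()]).
#' @param strict logical; `TRUE` uses `rotations > threshold`.
#' @param min_active_min minimum active minutes for a day to enter
#'   statistics (default 20; shorter days are flagged, mirroring adult
#'   physical-activity guidelines of ~20--40 min/day and screening out
#'   broken wheels).
#' @param speed_cap_kmh absolute plausibility cap on daily active speed
#'   (default 20 km/h, far above reported murine running speeds).
#' @param mad_k robust outlier multiplier: a day is flagged when its speed
#'   exceeds `median + mad_k * MAD` of the animal's other days.
#' @param hourly_bin_min bin width for hourly profiles (minutes).
#' @param actogram_bin_min bin width for actograms (minutes, default 10).
#' @param quantile_method `"nearest_rank"` (default) or `"type7"` for the
#'   quartile computations.
#' @param speed_method `"aggregate"` (total active distance over total
#'   active time; default) or `"per_minute_mean"`.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(wheel_diameter_m = 0.127,
                            circumference_m = pi * wheel_diameter_m,
                            active_threshold = 30,
                            threshold_mode = c("fixed", "quartile"),
                            strict = TRUE,
                            min_active_min = 20,
                            speed_cap_kmh = 20,
                            mad_k = 5,
                            hourly_bin_min = 60,
                            actogram_bin_min = 10,
                            quantile_method = c("nearest_rank", "type7"),
                            speed_method = c("aggregate", "per_minute_mean")) {
  vals <- c(wheel_diameter_m, circumference_m, active_threshold,
            min_active_min, speed_cap_kmh, mad_k, hourly_bin_min,
            actogram_bin_min)
  if (any(!is.finite(vals)) || any(vals[-3] <= 0) || active_threshold < 0)
    stop_validation("analysis_config values must be positive numbers")
  structure(list(wheel_diameter_m = wheel_diameter_m,
                 circumference_m = circumference_m,
                 active_threshold = active_threshold,
                 threshold_mode = match.arg(threshold_mode),
                 strict = isTRUE(strict),
                 min_active_min = min_active_min,
                 speed_cap_kmh = speed_cap_kmh,
                 mad_k = mad_k,
                 hourly_bin_min = hourly_bin_min,
                 actogram_bin_min = actogram_bin_min,
                 quantile_method = match.arg(quantile_method),
                 speed_method = match.arg(speed_method)),
            class = "analysis_config")
}

#' Derive the active-minute threshold from cohort data
#'
#' Computes the lower quartile (Q1) of per-minute rotation counts pooled
#' over the cohort, after excluding zero-rotation minutes (most minutes in
#' a wheel study are zero for every wheel, so a zero-inclusive quartile
#' would always be 0). The result is rounded to the nearest integer and
#' used as a strict threshold for chronic studies.
#'
#' @param counts integer vector of per-minute rotation counts pooled over
#'   all animals and days.
#' @param exclude_zeros drop zero minutes before taking the quartile
#'   (default `TRUE`).
#' @param method `"nearest_rank"` (Q1 is the `ceiling(n/4)`-th order
#'   statistic) or `"type7"` (R's default interpolating quantile).
#' @return integer threshold.
#' @export
derive_active_threshold <- function(counts, exclude_zeros = TRUE,
                                    method = c("nearest_rank", "type7")) {
  method <- match.arg(method)
  x <- counts[!is.na(counts)]
  if (exclude_zeros) x <- x[x > 0]
  if (length(x) == 0L)
    stop_validation("cannot derive a threshold: no nonzero minute counts")
  q1 <- if (method == "nearest_rank") {
    sort(x)[ceiling(length(x) / 4)]
  } else {
    stats::quantile(x, 0.25, names = FALSE, type = 7)
  }
  as.integer(round(q1))
}

#' Classify minutes as active
#'
#' A minute is active when its rotation count exceeds the threshold
#' (strictly by default: a minute with exactly `threshold` rotations is
#' inactive).
#'
#' @param rotations rotation counts (vectorised).
#' @param threshold activity threshold.
#' @param strict `TRUE` for `>`, `FALSE` for `>=`.
#' @return logical vector.
#' @export
classify_active <- function(rotations, threshold, strict = TRUE) {
  if (threshold < 0) stop_validation("`threshold` must be >= 0")
  if (strict) rotations > threshold else rotations >= threshold
}

summary_one_day <- function(rot, config, total_events = NA_real_) {
  circ <- config$circumference_m
  act <- classify_active(rot, config$active_threshold, config$strict)
  distance_km <- sum(rot) * circ / 1000
  active_min <- sum(act)
  speed <- if (active_min == 0) NA_real_
  else if (config$speed_method == "aggregate")
    (sum(rot[act]) * circ / 1000) / (active_min / 60)
  else mean(rot[act] * circ / 1000 * 60)
  data.frame(distance_km = distance_km, active_min = active_min,
             active_speed_kmh = speed, total_events = total_events)
}

#' Per-animal-day summaries of distance, duration and speed
#'
#' For every animal-day: distance (km) over *all* minutes, count of active
#' minutes, and active speed (km/h) computed only from active minutes --
#' by default total active distance divided by total active time.
#'
#' @param series stitched minute series (from [stitch_sessions()]), or any
#'   `data.frame` with `mouse_id`, `day_index` and `rotations` per minute.
#' @param config an [analysis_config()]. With
#'   `threshold_mode = "quartile"` the threshold is first derived from the
#'   pooled series via [derive_active_threshold()].
#' @return `data.frame`: `mouse_id`, `day_index`, `distance_km`,
#'   `active_min`, `active_speed_kmh`, `total_events` (NA when event
#'   counts are unavailable), plus the threshold used as attribute
#'   `active_threshold`.
#' @export
daily_summary <- function(series, config = analysis_config()) {
  need <- c("mouse_id", "day_index", "rotations")
  if (!all(need %in% names(series)))
    stop_validation(paste("`series` needs columns:",
                          paste(need, collapse = ", ")))
  if (config$threshold_mode == "quartile") {
    config$active_threshold <- derive_active_threshold(
      series$rotations, method = config$quantile_method)
  }
  has_events <- all(c("open_events", "close_events") %in% names(series))
  sp <- split(series, list(series$mouse_id, series$day_index), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    te <- if (has_events) sum(d$open_events + d$close_events) else NA_real_
    cbind(mouse_id = d$mouse_id[1], day_index = d$day_index[1],
          summary_one_day(d$rotations, config, te))
  }))
  out <- out[order(out$mouse_id, out$day_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "active_threshold") <- config$active_threshold
  out
}

#' Flag animal-days excluded from statistics
#'
#' Applies the analysis inclusion rules as auditable annotations (rows are
#' kept; downstream statistics drop flagged rows):
#' * `OFFLINE` -- the day recorded no switch events at all (broken or
#'   unplugged wheel);
#' * `TOO_FEW_ACTIVE_MIN` -- fewer than `min_active_min` active minutes;
#' * `SPEED_OUTLIER` -- active speed above the absolute cap
#'   `speed_cap_kmh`, or above `median + mad_k * MAD` of the same
#'   animal's other days (an implausible spike indicates equipment
#'   malfunction, not true speed).
#'
#' @param summaries output of [daily_summary()].
#' @param config an [analysis_config()].
#' @return `summaries` with added `excluded` (logical) and
#'   `exclusion_reason` (`"NONE"`, `"OFFLINE"`, `"TOO_FEW_ACTIVE_MIN"`,
#'   `"SPEED_OUTLIER"`).
#' @export
apply_exclusions <- function(summaries, config = analysis_config()) {
  s <- summaries
  s$exclusion_reason <- "NONE"
  spd <- s$active_speed_kmh
  for (id in unique(s$mouse_id)) {
    sel <- which(s$mouse_id == id)
    for (i in sel) {
      v <- spd[i]
      if (is.na(v)) next
      others <- spd[setdiff(sel, i)]
      others <- others[!is.na(others)]
      robust_hi <- if (length(others) >= 3)
        stats::median(others) + config$mad_k * stats::mad(others) else Inf
      if (v > config$speed_cap_kmh || v > robust_hi)
        s$exclusion_reason[i] <- "SPEED_OUTLIER"
    }
  }
  too_few <- s$active_min < config$min_active_min
  s$exclusion_reason[too_few] <- "TOO_FEW_ACTIVE_MIN"
  offline <- !is.na(s$total_events) & s$total_events == 0
  s$exclusion_reason[offline] <- "OFFLINE"
  s$excluded <- s$exclusion_reason != "NONE"
  s
}

#' Write a plain-text audit log of exclusions
#'
#' @param summaries output of [apply_exclusions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_exclusion_audit <- function(summaries, path) {
  ex <- summaries[summaries$excluded, , drop = FALSE]
  lines <- c(sprintf("# exclusion audit: %d of %d animal-days flagged",
                     nrow(ex), nrow(summaries)),
             sprintf("%s day %d: %s (active_min=%d, speed=%.3f km/h)",
                     ex$mouse_id, ex$day_index, ex$exclusion_reason,
                     ex$active_min,
                     ifelse(is.na(ex$active_speed_kmh), NaN,
                            ex$active_speed_kmh)))
  writeLines(lines, path)
  invisible(path)
}

#' Weekly group means with SEM
#'
#' Collapses daily summaries to animal-week means (over non-excluded days)
#' and then to group-week mean, SEM and n, with the animal as the
#' experimental unit (SEM = sample SD across animals / sqrt(n); reported
#' as `NA` when n = 1). Weeks are consecutive 7-session blocks from day 1;
#' a final short week (e.g. 6 sessions in a 13-day study) is kept.
#'
#' @param summaries output of [daily_summary()] or [apply_exclusions()]
#'   (rows with `excluded == TRUE` are dropped).
#' @param manifest animal manifest with `mouse_id` and the grouping
#'   columns.
#' @param by character vector of manifest columns defining groups
#'   (default `c("genotype", "sex")`).
#' @param metrics which daily columns to summarise.
#' @param week_len sessions per week (default 7).
#' @return long `data.frame`: `metric`, grouping columns, `week`, `mean`,
#'   `sem`, `n`.
#' @export
weekly_group_summary <- function(summaries, manifest,
                                 by = c("genotype", "sex"),
                                 metrics = c("distance_km", "active_min",
                                             "active_speed_kmh"),
                                 week_len = 7L) {
  if (!all(by %in% names(manifest)))
    stop_validation(paste("manifest lacks grouping column(s):",
                          paste(setdiff(by, names(manifest)), collapse = ", ")))
  s <- summaries
  if ("excluded" %in% names(s)) s <- s[!s$excluded, , drop = FALSE]
  s$week <- (s$day_index - 1L) %/% week_len + 1L
  s <- merge(s, manifest[, c("mouse_id", by), drop = FALSE], by = "mouse_id")
  grp_cols <- stats::setNames(lapply(by, function(b) s[[b]]), by)
  out <- list()
  for (m in metrics) {
    aw <- stats::aggregate(s[[m]],
                           by = c(list(mouse_id = s$mouse_id, week = s$week),
                                  grp_cols),
                           FUN = function(x) mean(x, na.rm = TRUE))
    names(aw)[ncol(aw)] <- "value"
    gs <- stats::aggregate(aw$value,
                           by = c(list(week = aw$week),
                                  stats::setNames(lapply(by, function(b)
                                    aw[[b]]), by)),
                           FUN = function(x) {
                             x <- x[is.finite(x)]
                             n <- length(x)
                             c(mean = mean(x),
                               sem = if (n > 1) stats::sd(x) / sqrt(n)
                                     else NA_real_,
                               n = n)
                           })
    res <- cbind(data.frame(metric = m), gs[c("week", by)])
    # aggregate stores the matrix result in the last column
    stats_mat <- gs[[ncol(gs)]]
    res$mean <- stats_mat[, "mean"]
    res$sem <- stats_mat[, "sem"]
    res$n <- as.integer(stats_mat[, "n"])
    out[[m]] <- res[order(interaction(res[by]), res$week), ]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hourly running-distance profile
#'
#' Averages running distance per clock hour over days per animal (giving a
#' 24-point km/h waveform) and then over animals per group, with SEM
#' across animals. Each hour's label is also expressed relative to
#' lights-off (zeitgeber-style, ZT12 = lights-off), computed from the
#' floor hour of `lights_off` -- shifting `lights_off` relabels the axis
#' but never changes the values.
#'
#' @param series stitched minute series with `timestamp`.
#' @param config an [analysis_config()] (wheel geometry).
#' @param lights_off clock time of lights-off, `"HH:MM"`.
#' @param manifest optional manifest for grouping.
#' @param by grouping columns in `manifest` (ignored when `manifest` is
#'   `NULL`; then each animal is its own group).
#' @param weeks optional integer vector restricting to these 7-session
#'   weeks.
#' @return `data.frame`: grouping columns, `hour` (0--23 clock hour),
#'   `zt_hour`, `dark` (logical), `mean_kmh`, `sem`, `n`.
#' @export
hourly_profile <- function(series, config = analysis_config(),
                           lights_off = "10:20", manifest = NULL,
                           by = "genotype", weeks = NULL) {
  if (!"timestamp" %in% names(series))
    stop_validation("`series` must carry absolute timestamps")
  s <- series
  if (!is.null(weeks)) {
    s <- s[((s$day_index - 1L) %/% 7L + 1L) %in% weeks, , drop = FALSE]
  }
  lt <- as.POSIXlt(s$timestamp, tz = "UTC")
  s$hour <- lt$hour
  circ <- config$circumference_m
  per_animal <- do.call(rbind, lapply(split(s, s$mouse_id), function(a) {
    n_days <- length(unique(a$day_index))
    agg <- stats::aggregate(a$rotations, by = list(hour = a$hour), FUN = sum)
    full <- merge(data.frame(hour = 0:23), agg, by = "hour", all.x = TRUE)
    full$x[is.na(full$x)] <- 0
    data.frame(mouse_id = a$mouse_id[1], hour = full$hour,
               kmh = full$x * circ / 1000 / n_days)
  }))
  if (!is.null(manifest)) {
    per_animal <- merge(per_animal, manifest[, c("mouse_id", by),
                                             drop = FALSE], by = "mouse_id")
  } else {
    by <- "mouse_id"
  }
  gs <- stats::aggregate(per_animal$kmh,
                         by = c(list(hour = per_animal$hour),
                                stats::setNames(lapply(by, function(b)
                                  per_animal[[b]]), by)),
                         FUN = function(x) c(mean = mean(x),
                                             sem = if (length(x) > 1)
                                               stats::sd(x) / sqrt(length(x))
                                             else NA_real_,
                                             n = length(x)))
  out <- gs[c("hour", by)]
  m <- gs[[ncol(gs)]]
  out$mean_kmh <- m[, "mean"]; out$sem <- m[, "sem"]; out$n <- as.integer(m[, "n"])
  off_h <- floor(clock_to_sec(lights_off) / 3600)
  out$zt_hour <- (out$hour - off_h + 12) %% 24
  off_s <- clock_to_sec(lights_off)
  hr_s <- out$hour * 3600
  out$dark <- ((hr_s - off_s) %% 86400) < 12 * 3600
  out <- out[order(interaction(out[by]), out$hour),
             c(by, "hour", "zt_hour", "dark", "mean_kmh", "sem", "n")]
  rownames(out) <- NULL
  out
}

#' Partition animals into High / Average / Low runners
#'
#' Ranks animals by total distance and labels the top quartile `High`, the
#' bottom quartile `Low`, and the middle two quartiles `Average`
#' (`floor(n/4)` animals per extreme quartile). Ties are broken by the
#' stable input order. Fewer than 4 animals cannot form quartiles: all are
#' labelled `Average` with a warning.
#'
#' @param totals named numeric vector of per-animal total distance (names
#'   are MouseIDs), or unnamed with `ids` supplied.
#' @param ids animal ids (defaults to `names(totals)`).
#' @return `data.frame`: `mouse_id`, `total`, `tier` in
#'   `c("High", "Average", "Low")`.
#' @export
quartile_partition <- function(totals, ids = names(totals)) {
  n <- length(totals)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  tier <- rep("Average", n)
  if (n < 4) {
    warning("fewer than 4 animals: degenerate partition, all 'Average'")
  } else {
    k <- n %/% 4
    ord <- order(totals, seq_len(n)) # stable tie-break by input order
    tier[ord[seq_len(k)]] <- "Low"
    tier[ord[seq(n - k + 1, n)]] <- "High"
  }
  data.frame(mouse_id = ids, total = as.numeric(totals), tier = tier,
             stringsAsFactors = FALSE)
}

#' Rotation-count distribution for density plots
#'
#' Returns the per-minute rotation counts used in rotation-density
#' figures, with their mean and median. Minutes with zero rotations are
#' excluded by default (the overwhelming majority of minutes are zero for
#' every wheel; the distribution of interest is over minutes when the
#' animal is on the wheel). No day-level exclusion filtering is applied.
#'
#' @param counts per-minute rotation counts.
#' @param exclude_zeros drop zero minutes (default `TRUE`).
#' @return list with `values`, `mean`, `median` (mean/median `NA` when no
#'   values remain).
#' @export
density_data <- function(counts, exclude_zeros = TRUE) {
  x <- counts[!is.na(counts)]
  if (exclude_zeros) x <- x[x > 0]
  list(values = x,
       mean = if (length(x)) mean(x) else NA_real_,
       median = if (length(x)) stats::median(x) else NA_real_)
}

#' Fraction of minutes with zero rotations
#'
#' @param rotations per-minute rotation counts (pooled over the dataset),
#'   or a series `data.frame` with a `rotations` column.
#' @return proportion of minutes with zero rotations.
#' @export
zero_minute_fraction <- function(rotations) {
  if (is.data.frame(rotations)) rotations <- rotations$rotations
  if (length(rotations) == 0L) stop_validation("empty series")
  mean(rotations == 0, na.rm = TRUE)
}
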