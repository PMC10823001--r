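# Reference CSV dialect for per-day logger session files: comma-separated,
# UNIX newlines, no quoting, header fixed to LOG_COLUMNS. Durations are
# written as integer milliseconds (the logger's own resolution).
LOG_COLUMNS <- c("minute", "channel", "open_events", "close_events",
                 "open_dur_ms", "closed_dur_ms", "rotations")

#' Write per-minute logger records to a session CSV file
#'
#' Writes one session (one logger, one day) in the reference dialect:
#' header `minute,channel,open_events,close_events,open_dur_ms,
#' closed_dur_ms,rotations`, comma-separated, UNIX newlines, no quoting.
#' Durations are rounded to integer milliseconds, so a written file
#' round-trips bit-stably through [read_log()].
#'
#' @param records minute-record `data.frame` (as from [decode_stream()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, path) {
  if (!all(LOG_COLUMNS %in% names(records)))
    stop_validation(paste("records must have columns:",
                          paste(LOG_COLUMNS, collapse = ", ")))
  out <- records[, LOG_COLUMNS]
  for (cl in LOG_COLUMNS) out[[cl]] <- as.integer(round(out[[cl]]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(LOG_COLUMNS, collapse = ","), con, sep = "\n")
  writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con,
             sep = "\n")
  invisible(path)
}

#' Read a logger session CSV file
#'
#' Parses a file written in the reference dialect (see [write_log()]).
#' Legacy files with differently named columns can be mapped via
#' `col_map`. Malformed rows fail with the offending line number.
#'
#' @param path file to read.
#' @param col_map optional named character vector mapping file column
#'   names to the canonical names, e.g. `c(min = "minute")`.
#' @return minute-record `data.frame` with the canonical columns.
#' @export
read_log <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop_usage(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop_validation(sprintf("%s: empty file", path))
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!is.null(col_map)) {
    m <- match(hdr, names(col_map))
    hdr[!is.na(m)] <- col_map[m[!is.na(m)]]
  }
  unknown <- setdiff(hdr, LOG_COLUMNS)
  if (length(unknown) > 0L)
    stop_validation(sprintf("%s: unknown column(s): %s", path,
                            paste(unknown, collapse = ", ")))
  if (!setequal(hdr, LOG_COLUMNS))
    stop_validation(sprintf("%s: missing column(s): %s", path,
                            paste(setdiff(LOG_COLUMNS, hdr), collapse = ", ")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(hdr))) {
    bad <- which(nf != length(hdr))[1]
    stop_validation(sprintf("%s: parse error at line %d (%d fields, expected %d)",
                            path, bad + 1L, nf[bad], length(hdr)))
  }
  vals <- suppressWarnings(
    matrix(as.integer(unlist(parts)), ncol = length(hdr), byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop_validation(sprintf("%s: parse error at line %d (non-numeric field)",
                            path, bad + 1L))
  }
  df <- as.data.frame(vals)
  names(df) <- hdr
  df[, LOG_COLUMNS]
}

#' Reconstruct absolute session start times from a manual reset log
#'
#' Loggers without a working real-time clock are reset by hand once per
#' day and the reset clock time written down; some entries may be missing.
#' Recorded days use their recorded time. Missing days are imputed as the
#' previous day's start plus a fixed interval: with
#' `fallback_interval_s = "auto"` that interval is the arithmetic mean of
#' all inter-reset gaps between adjacent recorded days; otherwise the
#' supplied constant in seconds. Leading missing days are imputed
#' backwards from the first recorded day. Every imputed entry is flagged.
#'
#' @param reset_log `data.frame` with columns `day_label` (dates, strictly
#'   increasing) and `reset_time` (`"HH:MM[:SS]"`, or `NA`/empty when the
#'   reset was not recorded).
#' @param fallback_interval_s `"auto"` or a positive number of seconds.
#' @return `data.frame` (`day_label`, `start` POSIXct UTC, `provenance`
#'   `"RECORDED"`/`"IMPUTED"`) with the interval used as attribute
#'   `interval_s`.
#' @export
build_timemap <- function(reset_log, fallback_interval_s = "auto") {
  if (!all(c("day_label", "reset_time") %in% names(reset_log)))
    stop_validation("`reset_log` needs columns day_label, reset_time")
  days <- as.Date(reset_log$day_label)
  if (anyNA(days)) stop_validation("unparseable day_label in reset log")
  if (any(diff(as.numeric(days)) <= 0))
    stop_validation("reset-log day_labels must be strictly increasing")
  tm <- as.character(reset_log$reset_time)
  recorded <- !is.na(tm) & nzchar(trimws(tm))
  n <- length(days)
  starts <- rep(as.POSIXct(NA), n)
  attr(starts, "tzone") <- "UTC"
  starts[recorded] <- as.POSIXct(days[recorded], tz = "UTC") +
    vapply(tm[recorded], clock_to_sec, numeric(1))
  if (identical(fallback_interval_s, "auto")) {
    adj <- which(recorded[-n] & recorded[-1])
    if (length(adj) == 0L)
      stop_validation(paste("cannot impute reset times: need at least two",
                            "adjacent recorded days for the mean interval"))
    interval <- mean(as.numeric(difftime(starts[adj + 1L], starts[adj],
                                         units = "secs")))
  } else {
    if (!is.numeric(fallback_interval_s) || fallback_interval_s <= 0)
      stop_validation("`fallback_interval_s` must be 'auto' or > 0 seconds")
    if (!any(recorded))
      stop_validation("cannot anchor the time map: no recorded reset at all")
    interval <- as.numeric(fallback_interval_s)
  }
  for (i in seq_len(n)[-1])      # forward chaining
    if (!recorded[i] && !is.na(starts[i - 1L]))
      starts[i] <- starts[i - 1L] + interval
  for (i in rev(seq_len(n - 1L))) # leading missing days
    if (is.na(starts[i])) starts[i] <- starts[i + 1L] - interval
  if (any(diff(as.numeric(starts)) <= 0))
    stop_validation("reconstructed session starts are not strictly increasing")
  out <- data.frame(day_label = days,
                    start = starts,
                    provenance = ifelse(recorded, "RECORDED", "IMPUTED"),
                    stringsAsFactors = FALSE)
  attr(out, "interval_s") <- interval
  out
}

#' Stitch daily session logs into per-animal timestamped series
#'
#' Joins minute records from per-day session files to the time map, giving
#' every record an absolute timestamp (session start + minute index), and
#' keys the result by MouseID (`"logger_channel"`). Sessions are never
#' resampled onto a fixed grid: a late reset simply shifts that day's
#' timestamps. Overlapping sessions on one logger are rejected. Channels
#' with no manifest entry are dropped with a warning; manifest animals
#' with no data produce a warning and an empty series.
#'
#' @param logs `data.frame` of minute records carrying `logger_id` and
#'   `day_label` columns in addition to the canonical record columns.
#' @param timemap output of [build_timemap()]; may carry a `logger_id`
#'   column, otherwise it applies to every logger.
#' @param manifest `data.frame` with at least `mouse_id` (and usually
#'   `sex`, `genotype`).
#' @return `data.frame`: `mouse_id`, `day_label`, `day_index` (session
#'   order per animal), `minute`, `timestamp` (POSIXct UTC), and the
#'   record columns; sorted by animal then time.
#' @export
stitch_sessions <- function(logs, timemap, manifest) {
  need <- c("logger_id", "day_label", "minute", "channel", "rotations")
  if (!all(need %in% names(logs)))
    stop_validation(paste("`logs` needs columns:", paste(need, collapse = ", ")))
  logs$day_label <- as.Date(logs$day_label)
  timemap$day_label <- as.Date(timemap$day_label)
  per_logger_map <- "logger_id" %in% names(timemap)
  key <- unique(logs[, c("logger_id", "day_label")])
  key$start <- as.POSIXct(NA)
  for (i in seq_len(nrow(key))) {
    tmrows <- if (per_logger_map)
      timemap[timemap$logger_id == key$logger_id[i] &
                timemap$day_label == key$day_label[i], , drop = FALSE]
    else timemap[timemap$day_label == key$day_label[i], , drop = FALSE]
    if (nrow(tmrows) == 0L)
      stop_validation(sprintf("no time-map entry for logger %s day %s",
                              key$logger_id[i], key$day_label[i]))
    key$start[i] <- tmrows$start[1]
  }
  # reject overlapping sessions per logger
  for (lg in unique(key$logger_id)) {
    k <- key[key$logger_id == lg, , drop = FALSE]
    k <- k[order(k$start), , drop = FALSE]
    if (nrow(k) > 1L) {
      dur <- vapply(seq_len(nrow(k) - 1L), function(i) {
        sel <- logs$logger_id == lg & logs$day_label == k$day_label[i]
        (max(logs$minute[sel]) + 1) * 60
      }, numeric(1))
      gap <- as.numeric(difftime(k$start[-1], k$start[-nrow(k)],
                                 units = "secs"))
      if (any(gap < dur))
        stop_validation(sprintf("overlapping sessions on logger %s", lg))
    }
  }
  logs <- merge(logs, key, by = c("logger_id", "day_label"))
  logs$timestamp <- logs$start + logs$minute * 60
  logs$start <- NULL
  logs$mouse_id <- paste(logs$logger_id, logs$channel, sep = "_")
  unknown <- setdiff(unique(logs$mouse_id), manifest$mouse_id)
  if (length(unknown) > 0L) {
    # warn only about unmanifested channels that actually carry data;
    # unused channels on a logger record all-zero rows and are dropped quietly
    active <- unique(logs$mouse_id[logs$rotations > 0 |
                                     (if ("close_events" %in% names(logs))
                                       logs$close_events > 0 else FALSE)])
    noisy <- intersect(unknown, active)
    if (length(noisy) > 0L)
      warning(sprintf("dropping channel(s) with no manifest entry: %s",
                      paste(noisy, collapse = ", ")))
    logs <- logs[logs$mouse_id %in% manifest$mouse_id, , drop = FALSE]
  }
  absent <- setdiff(manifest$mouse_id, unique(logs$mouse_id))
  if (length(absent) > 0L)
    warning(sprintf("manifest animal(s) with no logged data: %s",
                    paste(absent, collapse = ", ")))
  logs <- logs[order(logs$mouse_id, logs$timestamp), , drop = FALSE]
  # session order per animal
  logs$day_index <- ave(as.numeric(as.Date(logs$day_label)), logs$mouse_id,
                        FUN = function(x) match(x, sort(unique(x))))
  keep <- c("mouse_id", "day_label", "day_index", "minute", "timestamp",
            intersect(LOG_COLUMNS[-(1:2)], names(logs)))
  out <- logs[, keep]
  rownames(out) <- NULL
  out
}

#' Decode a simulated cohort and write its session files
#'
#' Runs the full logger data path on a simulated cohort: per logger and
#' day, the animals' event streams are decoded into minute records and
#' written as session CSV files, together with a manifest, a reset log
#' (optionally with missing entries, to exercise imputation), and a
#' ground-truth sidecar table.
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @param start_date date of session 1.
#' @param reset_time recorded reset clock time (`"HH:MM[:SS]"`).
#' @param missing_reset_days integer days whose reset entry is blanked.
#' @return invisibly, a list of the written file paths
#'   (`logs`, `manifest`, `resets`, `truth`).
#' @export
write_cohort_logs <- function(cohort, dir,
                              start_date = "2024-03-04",
                              reset_time = cohort$sims[[1]]$params$lights_off,
                              missing_reset_days = integer()) {
  stopifnot(inherits(cohort, "wheel_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_days <- cohort$sims[[1]]$params$n_days
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  cfg <- cohort$logger_config
  log_paths <- character(0)
  for (lg in sort(unique(cohort$manifest$logger))) {
    ids <- cohort$manifest$mouse_id[cohort$manifest$logger == lg]
    for (d in seq_len(n_days)) {
      ev <- do.call(rbind, lapply(ids, function(id) cohort$events[[id]][[d]]))
      ev <- ev[order(ev$channel, ev$t_ms), , drop = FALSE]
      recs <- decode_stream(ev, cfg, n_minutes = 1440L)
      p <- file.path(dir, sprintf("log%d_%s.csv", lg, dates[d]))
      write_log(recs, p)
      log_paths <- c(log_paths, p)
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, manifest_path, row.names = FALSE,
                   quote = FALSE)
  rt <- rep(reset_time, n_days)
  rt[missing_reset_days] <- ""
  resets_path <- file.path(dir, "resets.csv")
  utils::write.csv(data.frame(day_label = dates, reset_time = rt),
                   resets_path, row.names = FALSE, quote = FALSE)
  truth <- do.call(rbind, lapply(names(cohort$sims), function(id) {
    tr <- cohort$sims[[id]]$truth
    cbind(mouse_id = id, tr)
  }))
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(logs = log_paths, manifest = manifest_path,
                 resets = resets_path, truth = truth_path))
}

#' Read all session files in a directory into one record table
#'
#' Reads every file matching `log<logger>_<date>.csv` and binds the
#' records with `logger_id` and `day_label` columns, ready for
#' [stitch_sessions()].
#'
#' @param dir directory containing session files.
#' @param col_map passed to [read_log()].
#' @return `data.frame` of minute records with `logger_id`, `day_label`.
#' @export
read_log_dir <- function(dir, col_map = NULL) {
  files <- list.files(dir, pattern = "^log[0-9]+_[0-9-]+\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop_usage(sprintf("no session files (log<id>_<date>.csv) in %s", dir))
  out <- lapply(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^log([0-9]+)_([0-9-]+)\\.csv$", basename(f)))[[1]]
    recs <- read_log(f, col_map = col_map)
    cbind(logger_id = as.integer(m[2]), day_label = as.Date(m[3]), recs)
  })
  do.call(rbind, out)
}
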