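#' Actogram matrix for one animal
#'
#' Bins one animal's minute series into 10-min (by default) bins of
#' rotations, one row per calendar day, columns anchored to clock
#' midnight. When `double_plot = TRUE` each row shows two consecutive
#' days side by side (the classic double-plotted actogram), so row *d*'s
#' right half equals row *d + 1*'s left half wherever both days exist.
#' Bins never covered by data are `NA` (missing is distinguished from
#' zero); a session that starts mid-day therefore yields a partially
#' masked first row.
#'
#' @param series stitched minute series for a single animal (`timestamp`,
#'   `rotations`).
#' @param bin_min bin width in minutes; must divide 1440 (default 10).
#' @param double_plot logical (default `TRUE`).
#' @param lights_off clock time of lights-off for the light mask.
#' @param photoperiod_h hours of darkness.
#' @return numeric matrix (days x bins) of class `actogram_matrix` with
#'   attributes `light_mask` (logical per column; `TRUE` = lights on),
#'   `bin_min`, `days`.
#' @export
actogram_matrix <- function(series, bin_min = 10, double_plot = TRUE,
                            lights_off = "10:20", photoperiod_h = 12) {
  if (1440 %% bin_min != 0)
    stop_validation("`bin_min` must divide 1440")
  if (length(unique(series$mouse_id)) > 1)
    stop_validation("actogram_matrix expects a single animal's series")
  nb <- 1440L %/% as.integer(bin_min)
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  day <- as.Date(series$timestamp, tz = "UTC")
  bin <- (lt$hour * 60L + lt$min) %/% as.integer(bin_min)
  days <- seq(min(day), max(day), by = "day") # gap days stay as NA rows
  mat <- matrix(NA_real_, nrow = length(days), ncol = nb,
                dimnames = list(as.character(days), NULL))
  di <- match(day, days)
  for (k in seq_along(bin)) {
    v <- mat[di[k], bin[k] + 1L]
    mat[di[k], bin[k] + 1L] <- if (is.na(v)) series$rotations[k]
                               else v + series$rotations[k]
  }
  if (double_plot) {
    nxt <- rbind(mat[-1, , drop = FALSE],
                 matrix(NA_real_, 1, nb))
    mat <- cbind(mat, nxt)
  }
  # light mask per column: TRUE where lights are on
  off_s <- clock_to_sec(lights_off)
  bin_start_s <- (seq_len(nb) - 1L) * bin_min * 60
  dark <- ((bin_start_s - off_s) %% 86400) < photoperiod_h * 3600
  mask <- !dark
  if (double_plot) mask <- c(mask, mask)
  structure(mat, light_mask = mask, bin_min = bin_min,
            days = days, class = c("actogram_matrix", "matrix", "array"))
}

#' Cohort heatmap matrix
#'
#' Bins every animal's series onto one common study clock: rows are
#' MouseIDs (sorted), columns are consecutive bins from midnight of the
#' first study day to the end of the last, values are rotations per bin
#' (`NA` where an animal has no data -- offline periods are masked, not
#' zero). Row sums times the wheel circumference reproduce per-animal
#' total distance.
#'
#' @param series stitched minute series for the whole cohort.
#' @param bin_min bin width in minutes (default 10).
#' @param rate_scale multiply counts by `60 / bin_min` to express values
#'   as rotations/hour instead of counts per bin (default `FALSE`).
#' @return numeric matrix of class `heatmap_matrix` with attribute
#'   `bin_start` (POSIXct of each column's left edge).
#' @export
heatmap_matrix <- function(series, bin_min = 10, rate_scale = FALSE) {
  if (1440 %% bin_min != 0)
    stop_validation("`bin_min` must divide 1440")
  ids <- sort(unique(series$mouse_id))
  origin <- as.POSIXct(min(as.Date(series$timestamp, tz = "UTC")), tz = "UTC")
  bin_s <- bin_min * 60
  off <- as.numeric(difftime(series$timestamp, origin, units = "secs"))
  col <- floor(off / bin_s) + 1L
  ncol <- max(col)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = ncol,
                dimnames = list(ids, NULL))
  ri <- match(series$mouse_id, ids)
  for (k in seq_along(col)) {
    v <- mat[ri[k], col[k]]
    mat[ri[k], col[k]] <- if (is.na(v)) series$rotations[k]
                          else v + series$rotations[k]
  }
  if (rate_scale) mat <- mat * 60 / bin_min
  structure(mat, bin_start = origin + (seq_len(ncol) - 1L) * bin_s,
            bin_min = bin_min,
            class = c("heatmap_matrix", "matrix", "array"))
}

#' Write a figure matrix as CSV
#'
#' Sidecar export so figure data can be inspected and diffed; values are
#' written exactly as stored (missing bins as empty fields).
#'
#' @param mat an [actogram_matrix()] or [heatmap_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  utils::write.csv(unclass(mat)[, , drop = FALSE], path, row.names = TRUE,
                   na = "")
  invisible(path)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         png = grDevices::png(path, width = width * 96, height = height * 96,
                              res = 96),
         stop_usage(sprintf("unsupported image format '.%s'", ext)))
}

#' Plot a double-plotted actogram
#'
#' Renders rows of per-bin activity bars, one line per day, with the
#' lights-on portion of the cycle shaded. Bar heights are scaled to each
#' row's maximum (classic actogram convention). Missing bins are left
#' blank.
#'
#' @param mat an [actogram_matrix()].
#' @param path optional output image path (`.png`, `.svg` or `.pdf`); when
#'   `NULL`, draws on the current device.
#' @param main plot title.
#' @param shade_col colour for the lights-on shading.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_actogram <- function(mat, path = NULL, main = "Actogram",
                          shade_col = "lemonchiffon") {
  stopifnot(inherits(mat, "actogram_matrix"))
  if (!is.null(path)) {
    open_device(path, 7, 5)
    on.exit(grDevices::dev.off())
  }
  m <- unclass(mat)
  nd <- nrow(m); nb <- ncol(m)
  mask <- attr(mat, "light_mask")
  graphics::plot(NULL, xlim = c(0, nb), ylim = c(nd, 0), xaxs = "i",
                 yaxs = "i", xlab = "Time of day (h)", ylab = "Day",
                 main = main, axes = FALSE)
  hours <- seq(0, nb * attr(mat, "bin_min") / 60, by = 6)
  graphics::axis(1, at = hours * 60 / attr(mat, "bin_min"),
                 labels = hours %% 24)
  graphics::axis(2, at = seq_len(nd) - 0.5, labels = rownames(m), las = 1,
                 cex.axis = 0.6)
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  for (i in seq_along(r$values))
    if (r$values[i])
      graphics::rect(starts[i], nd, ends[i], 0, col = shade_col,
                     border = NA)
  for (d in seq_len(nd)) {
    row <- m[d, ]
    mx <- max(row, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) mx <- 1
    h <- 0.9 * row / mx
    ok <- which(!is.na(row) & row > 0)
    if (length(ok))
      graphics::rect(ok - 1, d, ok, d - h[ok], col = "black", border = NA)
  }
  graphics::box()
  invisible(path)
}

#' Plot a cohort activity heatmap
#'
#' @param mat a [heatmap_matrix()].
#' @param path optional output image path.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_heatmap <- function(mat, path = NULL, main = "Wheel rotations") {
  stopifnot(inherits(mat, "heatmap_matrix"))
  if (!is.null(path)) {
    open_device(path, 8, 4)
    on.exit(grDevices::dev.off())
  }
  m <- unclass(mat)
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m), col = pal, xlab = "Bin", ylab = "",
                  main = main, axes = FALSE, useRaster = TRUE)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 1,
                 cex.axis = 0.6)
  graphics::axis(1)
  graphics::box()
  invisible(path)
}

#' Plot a rotation-density curve with mean and median markers
#'
#' Kernel density of nonzero per-minute rotation counts, with a vertical
#' red line at the mean and a blue line at the median. An empty input
#' renders a labelled empty-state placeholder rather than failing.
#'
#' @param dens output of [density_data()].
#' @param path optional output image path.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_density_rotations <- function(dens, path = NULL,
                                   main = "Wheel rotations per active minute") {
  if (!is.null(path)) {
    open_device(path, 6, 4)
    on.exit(grDevices::dev.off())
  }
  x <- dens$values
  if (length(x) < 2) {
    graphics::plot(NULL, xlim = 0:1, ylim = 0:1, axes = FALSE, xlab = "",
                   ylab = "", main = main)
    graphics::text(0.5, 0.5, "no active minutes")
    graphics::box()
  } else {
    d <- stats::density(x, from = 0)
    graphics::plot(d, main = main, xlab = "Rotations/min", ylab = "Density")
    graphics::abline(v = dens$mean, col = "red", lwd = 2)
    graphics::abline(v = dens$median, col = "blue", lwd = 2)
  }
  invisible(path)
}

#' Plot an hourly running-distance profile
#'
#' @param profile output of [hourly_profile()]; one line per group with
#'   SEM whiskers, dark hours shaded grey.
#' @param path optional output image path.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_hourly_profile <- function(profile, path = NULL,
                                main = "Hourly running distance") {
  if (!is.null(path)) {
    open_device(path, 6, 4)
    on.exit(grDevices::dev.off())
  }
  grp_cols <- setdiff(names(profile),
                      c("hour", "zt_hour", "dark", "mean_kmh", "sem", "n"))
  key <- interaction(profile[grp_cols], drop = TRUE)
  ymax <- max(profile$mean_kmh + ifelse(is.na(profile$sem), 0, profile$sem),
              0.01)
  graphics::plot(NULL, xlim = c(0, 23), ylim = c(0, 1.05 * ymax),
                 xlab = "Clock hour", ylab = "km/h", main = main)
  dark_h <- sort(unique(profile$hour[profile$dark]))
  if (length(dark_h))
    graphics::rect(dark_h - 0.5, 0, dark_h + 0.5, 1.05 * ymax,
                   col = "grey92", border = NA)
  cols <- grDevices::hcl.colors(max(2L, nlevels(key)), "Dark 3")
  for (i in seq_len(nlevels(key))) {
    p <- profile[key == levels(key)[i], ]
    p <- p[order(p$hour), ]
    graphics::lines(p$hour, p$mean_kmh, col = cols[i], lwd = 2)
    ok <- !is.na(p$sem)
    graphics::arrows(p$hour[ok], p$mean_kmh[ok] - p$sem[ok], p$hour[ok],
                     p$mean_kmh[ok] + p$sem[ok], angle = 90, code = 3,
                     length = 0.02, col = cols[i])
  }
  graphics::legend("topright", legend = levels(key), col = cols[seq_len(nlevels(key))],
                   lwd = 2, bty = "n", cex = 0.8)
  graphics::box()
  invisible(path)
}
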