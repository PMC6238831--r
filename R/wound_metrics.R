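# Dated wound measurements, the longitudinal progress series, the 4-week
# healing assessment, and reminder scheduling.  The headline quantity is
# the ulcer area both in cm^2 (via the sticker scale) and as a fraction of
# the foot silhouette area, and the percent area reduction over the first
# 4 weeks of care: a reduction greater than 50% is the accepted surrogate
# marker of effective diabetic-foot-ulcer healing.

#' Combine segmentations and scale into a dated wound measurement
#'
#' @param ulcer_seg An `"ulcer_segmentation"`.
#' @param foot_seg A `"foot_segmentation"`; every ulcer pixel must lie
#'   inside the foot mask.
#' @param scale A `"scale_estimate"`.
#' @param date Measurement date (`Date` or ISO-8601 string).
#' @return One-row data frame of class `"wound_measurement"` with columns
#'   `date`, `ulcer_area_px`, `foot_area_px`, `pixels_per_cm`,
#'   `ulcer_area_cm2`, `area_ratio`.
#' @export
measure <- function(ulcer_seg, foot_seg, scale, date) {
  stopifnot(inherits(ulcer_seg, "ulcer_segmentation"),
            inherits(foot_seg, "foot_segmentation"))
  if (any(ulcer_seg$ulcer_mask & !foot_seg$foot_mask))
    um_stop("um_containment_violation",
            "ulcer pixels fall outside the foot mask")
  up <- ulcer_seg$n_ulcer_px
  fp <- foot_seg$foot_area_px
  out <- data.frame(date = as.Date(date),
                    ulcer_area_px = up,
                    foot_area_px = fp,
                    pixels_per_cm = scale$pixels_per_cm,
                    ulcer_area_cm2 = px_area_to_cm2(up, scale),
                    area_ratio = up / fp)
  class(out) <- c("wound_measurement", "data.frame")
  out
}

#' Progress series of wound measurements
#'
#' @param measurements Data frame with at least columns `date` and
#'   `ulcer_area_cm2` (e.g. rows from [measure()] or a measurement log);
#'   dates must be strictly increasing after coercion with `as.Date`.
#' @return Data frame of class `"progress_series"`, sorted by date.
#' @export
progress_series <- function(measurements) {
  df <- as.data.frame(measurements)
  stopifnot(nrow(df) >= 1L,
            all(c("date", "ulcer_area_cm2") %in% names(df)))
  df$date <- as.Date(df$date)
  df <- df[order(df$date), , drop = FALSE]
  if (anyDuplicated(df$date))
    um_stop("um_error", "measurement dates must be strictly increasing")
  rownames(df) <- NULL
  class(df) <- c("progress_series", "data.frame")
  df
}

#' Assess healing against the 4-week >50% area-reduction marker
#'
#' The baseline is the earliest measurement.  The assessment point is the
#' measurement closest to `baseline date + window_days` within
#' `+/- tolerance_days` (nearest wins; the earlier measurement wins
#' ties).  `on_track` is true iff the percent area reduction from
#' baseline strictly exceeds `threshold_pct`.
#'
#' @param series A [progress_series()].
#' @param window_days Assessment horizon in days (default 28).
#' @param tolerance_days Acceptable distance from the horizon (default 3).
#' @param threshold_pct Reduction threshold in percent (default 50;
#'   strict inequality).
#' @return List of class `"healing_assessment"`.
#' @export
assess_healing <- function(series, window_days = 28L, tolerance_days = 3L,
                           threshold_pct = 50) {
  s <- progress_series(series)
  if (nrow(s) < 2L)
    um_stop("um_no_assessment_point",
            "series needs a baseline and at least one later measurement")
  baseline <- s[1L, ]
  target <- baseline$date + window_days
  dist <- abs(as.numeric(s$date - target))
  cand <- which(dist <= tolerance_days & s$date > baseline$date)
  if (length(cand) == 0L)
    um_stop("um_no_assessment_point",
            sprintf("no measurement within %d days of day %d",
                    tolerance_days, window_days))
  best <- cand[order(dist[cand], s$date[cand])][1L]  # nearest, earlier on tie
  assessment <- s[best, ]
  if (baseline$ulcer_area_cm2 <= 0)
    um_stop("um_zero_baseline", "baseline ulcer area is zero")
  pr <- 100 * (baseline$ulcer_area_cm2 - assessment$ulcer_area_cm2) /
    baseline$ulcer_area_cm2
  out <- list(baseline_date = baseline$date,
              baseline_area_cm2 = baseline$ulcer_area_cm2,
              assessment_date = assessment$date,
              assessment_area_cm2 = assessment$ulcer_area_cm2,
              percent_reduction = pr,
              on_track = pr > threshold_pct,
              threshold_pct = threshold_pct)
  class(out) <- "healing_assessment"
  out
}

#' @export
print.healing_assessment <- function(x, ...) {
  cat(sprintf("Healing assessment (%s to %s):\n",
              format(x$baseline_date), format(x$assessment_date)))
  cat(sprintf("  area %.3f cm2 -> %.3f cm2: %.1f%% reduction\n",
              x$baseline_area_cm2, x$assessment_area_cm2,
              x$percent_reduction))
  cat(sprintf("  on track (> %.0f%% reduction): %s\n", x$threshold_pct,
              if (x$on_track) "yes" else "no"))
  invisible(x)
}

#' Percent-of-baseline curve for the progress graph
#'
#' @param series A [progress_series()].
#' @return Data frame with columns `date` and `percent_of_baseline`
#'   (first entry 100).
#' @export
percent_change_curve <- function(series) {
  s <- progress_series(series)
  base <- s$ulcer_area_cm2[1L]
  if (base <= 0) um_stop("um_zero_baseline", "baseline ulcer area is zero")
  data.frame(date = s$date,
             percent_of_baseline = 100 * s$ulcer_area_cm2 / base)
}

#' Reminder configuration
#'
#' @param interval Positive interval between reminders, as a `difftime`
#'   or a number of minutes.
#' @param anchor Timestamp (`POSIXct`) of the last completed event.
#' @param message Notification text shown to the patient.
#' @return List of class `"reminder_config"`.
#' @export
reminder_config <- function(interval, anchor,
                            message = "Time to check your foot") {
  if (inherits(interval, "difftime"))
    interval_min <- as.numeric(interval, units = "mins")
  else interval_min <- as.numeric(interval)
  if (!is.finite(interval_min) || interval_min <= 0)
    um_stop("um_error", "reminder interval must be positive")
  out <- list(interval_min = interval_min,
              anchor = as.POSIXct(anchor, tz = "UTC"),
              message = message)
  class(out) <- "reminder_config"
  out
}

#' Next reminder due time
#'
#' Returns `anchor + k * interval` for the smallest integer `k >= 1` with
#' a result strictly after `now`, so a query exactly on a due time
#' returns the following one.
#'
#' @param config A [reminder_config()].
#' @param now Current timestamp.
#' @return `POSIXct` due time.
#' @export
next_reminder <- function(config, now) {
  stopifnot(inherits(config, "reminder_config"))
  now <- as.POSIXct(now, tz = "UTC")
  step <- config$interval_min * 60
  elapsed <- as.numeric(difftime(now, config$anchor, units = "secs"))
  k <- max(1, floor(elapsed / step) + 1)
  due <- config$anchor + k * step
  if (due <= now) due <- due + step
  due
}

#' Read / append a measurement log CSV
#'
#' Columns: `date, ulcer_area_px, foot_area_px, pixels_per_cm,
#' ulcer_area_cm2, area_ratio`.  Appends are atomic: the updated log is
#' written to a temporary file and renamed over the original, so a
#' failing run never leaves a partial row.
#'
#' @param path CSV path.
#' @param measurement A [measure()] row.
#' @return `read_measurement_log`: a [progress_series()].
#' @export
read_measurement_log <- function(path) {
  progress_series(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurement_log
#' @export
append_measurement_log <- function(measurement, path) {
  new_row <- as.data.frame(measurement)
  new_row$date <- format(as.Date(new_row$date))
  df <- if (file.exists(path))
    rbind(read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(date = "character")), new_row)
  else new_row
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Plot the wound-progress graph
#'
#' Two stacked panels: absolute ulcer area (cm^2) over time and percent
#' of baseline over time, with the 50% line marked.
#'
#' @param series A [progress_series()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_progress <- function(series, path) {
  s <- progress_series(series)
  curve <- percent_change_curve(s)
  png(path, width = 800, height = 600)
  on.exit(dev.off())
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op), add = TRUE, after = FALSE)
  plot(s$date, s$ulcer_area_cm2, type = "b", pch = 19, col = "firebrick",
       xlab = "date", ylab = "ulcer area (cm2)", main = "Wound progress")
  plot(curve$date, curve$percent_of_baseline, type = "b", pch = 19,
       col = "steelblue", ylim = c(0, max(100, curve$percent_of_baseline)),
       xlab = "date", ylab = "% of baseline area")
  abline(h = 50, lty = 2)
  mtext("50% of baseline", side = 4, at = 50, las = 1, cex = 0.7)
  invisible(path)
}
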