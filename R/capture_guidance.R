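# Capture guidance.  The phone lies on the floor with the camera facing
# up and the patient hovers the foot above it; the app tells the patient
# to move the foot HIGHER (silhouette too large: foot too close), LOWER
# (too small: foot too far), CENTER it, HOLD while a stability counter
# runs, and finally CAPTURED.  Tokens are symbolic; voice output is out
# of scope.

GUIDANCE_TOKENS <- c("HIGHER", "LOWER", "CENTER", "HOLD", "CAPTURED",
                     "NO_FOOT")

#' Guidance configuration
#'
#' @param fraction_band `(f_lo, f_hi)` target band for the fraction of
#'   the frame covered by the foot silhouette (default 0.25--0.45).
#' @param center_tolerance_px Maximum absolute centroid offset from the
#'   image center on either axis; `NULL` (default) resolves to 10% of the
#'   smaller image dimension at analysis time.
#' @param stability_frames Number of consecutive compliant frames before
#'   automatic capture (default 3).
#' @return List of class `"guidance_config"`.
#' @export
guidance_config <- function(fraction_band = c(0.25, 0.45),
                            center_tolerance_px = NULL,
                            stability_frames = 3L) {
  stopifnot(length(fraction_band) == 2L,
            fraction_band[1] > 0, fraction_band[1] < fraction_band[2],
            fraction_band[2] < 1, stability_frames >= 1L)
  out <- list(fraction_band = as.numeric(fraction_band),
              center_tolerance_px = center_tolerance_px,
              stability_frames = as.integer(stability_frames))
  class(out) <- "guidance_config"
  out
}

#' Per-frame metrics for capture guidance
#'
#' Runs [segment_foot()]; a frame in which no foot is found yields
#' `foot_found = FALSE` and fraction 0 rather than an error.
#'
#' @param image Integer `H x W x 3` array.
#' @return List of class `"frame_metrics"`: `foot_found`, `foot_fraction`
#'   (silhouette px / frame px), `centroid_offset` (`(d_row, d_col)` from
#'   the image center, px), `image_size` (`(H, W)`).
#' @export
analyze_frame <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  seg <- tryCatch(segment_foot(image), um_no_foot = function(e) NULL)
  out <- if (is.null(seg))
    list(foot_found = FALSE, foot_fraction = 0,
         centroid_offset = c(NA_real_, NA_real_), image_size = c(H, W))
  else
    list(foot_found = TRUE,
         foot_fraction = seg$foot_area_px / (H * W),
         centroid_offset = seg$foot_centroid_px - c((H + 1) / 2, (W + 1) / 2),
         image_size = c(H, W))
  class(out) <- "frame_metrics"
  out
}

#' One step of the guidance state machine
#'
#' Decision order: no foot -> `NO_FOOT`; fraction above the band ->
#' `HIGHER` (foot too close to the upward-facing camera); below the band
#' -> `LOWER`; centroid off-center beyond tolerance on either axis ->
#' `CENTER`; otherwise the stability counter advances and the token is
#' `HOLD` until the counter reaches `stability_frames`, which emits
#' `CAPTURED`.  Any non-compliant frame resets the counter.
#'
#' @param metrics A [analyze_frame()] result.
#' @param config A [guidance_config()].
#' @param state Consecutive-in-band counter (0 at session start).
#' @return List `token`, `state` (updated counter).
#' @export
guidance_step <- function(metrics, config, state = 0L) {
  stopifnot(inherits(config, "guidance_config"))
  tol <- config$center_tolerance_px
  if (is.null(tol)) tol <- 0.10 * min(metrics$image_size)
  band <- config$fraction_band
  if (!metrics$foot_found)
    return(list(token = "NO_FOOT", state = 0L))
  if (metrics$foot_fraction > band[2])
    return(list(token = "HIGHER", state = 0L))
  if (metrics$foot_fraction < band[1])
    return(list(token = "LOWER", state = 0L))
  if (any(abs(metrics$centroid_offset) > tol))
    return(list(token = "CENTER", state = 0L))
  state <- state + 1L
  if (state >= config$stability_frames)
    list(token = "CAPTURED", state = state)
  else
    list(token = "HOLD", state = state)
}

#' Run a guidance session over a frame sequence
#'
#' Folds [guidance_step()] over the frames and stops at the first
#' `CAPTURED`, so `CAPTURED` is emitted at most once per session.
#'
#' @param frames List of `H x W x 3` image arrays.
#' @param config A [guidance_config()].
#' @return List of class `"guidance_session"`: `signals` (character
#'   vector, one token per processed frame) and `captured_index` (index
#'   of the capturing frame, or `NA` if the session ends uncaptured).
#' @export
run_session <- function(frames, config = guidance_config()) {
  stopifnot(length(frames) >= 1L)
  signals <- character(0)
  state <- 0L
  captured <- NA_integer_
  for (i in seq_along(frames)) {
    step <- guidance_step(analyze_frame(frames[[i]]), config, state)
    signals <- c(signals, step$token)
    state <- step$state
    if (step$token == "CAPTURED") { captured <- i; break }
  }
  out <- list(signals = signals, captured_index = captured)
  class(out) <- "guidance_session"
  out
}

#' @export
print.guidance_session <- function(x, ...) {
  cat(sprintf("Guidance session: %d frame(s)\n", length(x$signals)))
  cat("  ", paste(x$signals, collapse = " "), "\n", sep = "")
  if (is.na(x$captured_index)) cat("  no capture\n")
  else cat(sprintf("  captured at frame %d\n", x$captured_index))
  invisible(x)
}
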