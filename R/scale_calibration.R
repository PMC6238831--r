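# Fiducial-sticker scale calibration.  A solid green circular sticker of
# known 1-cm physical diameter is placed on the foot; detecting it fixes
# the pixels-per-centimetre factor used for all wound-size conversions.

#' Per-pixel green-dominance classification
#'
#' A pixel is classified green iff `G > ratio * R`, `G > ratio * B` and
#' `G >= g_min` on 8-bit channel values.  Pure per-pixel rule with no
#' spatial context.
#'
#' @param image Integer `H x W x 3` array, values 0--255.
#' @param ratio Dominance ratio of green over red and blue (default 1.3).
#' @param g_min Minimum absolute green level (default 60).
#' @return Logical `H x W` mask.
#' @export
classify_green <- function(image, ratio = 1.3, g_min = 60) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  m <- G > ratio * R & G > ratio * B & G >= g_min
  dim(m) <- dim(image)[1:2]
  m
}

#' Detect the 1-cm green sticker and estimate the image scale
#'
#' 8-connected components of the green mask are filtered by minimum area
#' and by circularity `4 pi A / P^2`, where `A` is the pixel count and `P`
#' is the component's boundary perimeter: the count of unit edge segments
#' between component and non-component pixels, multiplied by the
#' Cauchy-Crofton factor `pi / 4` that maps the axis-aligned edge count of
#' a convex digitized shape to its Euclidean perimeter (a digitized disc
#' then scores ~1).  The largest surviving component is taken as the
#' sticker; its diameter is the equivalent-circle diameter
#' `2 sqrt(A / pi)`, and since the physical diameter is 1 cm,
#' `pixels_per_cm` equals that diameter.
#'
#' @param image Integer `H x W x 3` array.
#' @param min_area_px Minimum component area (default 50).
#' @param min_circularity Circularity acceptance threshold (default 0.7).
#' @param ambiguity_fraction Two or more surviving components with areas
#'   within this fraction of each other raise an ambiguity error
#'   (default 0.2).
#' @param green_ratio,green_min Passed to [classify_green()].
#' @return Object of class `"scale_estimate"`: `pixels_per_cm`,
#'   `sticker_center_px`, `sticker_diameter_px`, `circularity`,
#'   `n_candidate_components`.
#' @export
detect_sticker <- function(image, min_area_px = 50, min_circularity = 0.7,
                           ambiguity_fraction = 0.2,
                           green_ratio = 1.3, green_min = 60) {
  mask <- classify_green(image, ratio = green_ratio, g_min = green_min)
  labels <- cpp_label_components(mask, 8L)
  nlab <- max(labels)
  if (nlab == 0L)
    um_stop("um_no_sticker", "no green sticker found in the image")
  areas <- tabulate(labels[labels > 0L], nbins = nlab)
  per_edges <- cpp_component_perimeters(labels, nlab)
  per <- per_edges * pi / 4
  circ <- pmin(1, 4 * pi * areas / per^2)
  survive <- which(areas >= min_area_px & circ >= min_circularity)
  if (length(survive) == 0L)
    um_stop("um_no_sticker",
            "no green component passes the area and circularity filters")
  if (length(survive) >= 2L) {
    a <- sort(areas[survive], decreasing = TRUE)
    if (abs(a[1] - a[2]) / a[1] <= ambiguity_fraction)
      um_stop("um_ambiguous_sticker",
              sprintf("%d candidate stickers with similar areas (%d and %d px)",
                      length(survive), a[1], a[2]))
  }
  best <- survive[which.max(areas[survive])]
  A <- areas[best]
  diameter <- 2 * sqrt(A / pi)
  out <- list(pixels_per_cm = diameter,
              sticker_center_px = mask_centroid(labels == best),
              sticker_diameter_px = diameter,
              circularity = circ[best],
              n_candidate_components = length(survive))
  class(out) <- "scale_estimate"
  out
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf(paste0("Scale estimate: %.2f px/cm ",
                     "(sticker diameter %.2f px, circularity %.3f, ",
                     "%d candidate component%s)\n"),
              x$pixels_per_cm, x$sticker_diameter_px, x$circularity,
              x$n_candidate_components,
              if (x$n_candidate_components == 1) "" else "s"))
  cat(sprintf("  sticker center: (%.1f, %.1f)\n",
              x$sticker_center_px[1], x$sticker_center_px[2]))
  invisible(x)
}

#' Convert a pixel area to square centimetres
#'
#' @param area_px Nonnegative pixel count.
#' @param scale A `"scale_estimate"` (or any list with a positive
#'   `pixels_per_cm`).
#' @return `area_px / pixels_per_cm^2`.
#' @export
px_area_to_cm2 <- function(area_px, scale) {
  ppc <- scale$pixels_per_cm
  if (!is.numeric(ppc) || length(ppc) != 1L || ppc <= 0)
    um_stop("um_error", "pixels_per_cm must be a positive scalar")
  stopifnot(all(area_px >= 0))
  area_px / ppc^2
}
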