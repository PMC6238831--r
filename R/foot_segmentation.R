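# Foot-silhouette segmentation.  The capture protocol uses the phone
# flash to illuminate the foot and keep the background dark, so the
# luminance histogram is strongly bimodal and a global Otsu threshold
# separates foot from background.

#' Segment the foot silhouette from the dark background
#'
#' Pipeline: Rec. 601 luminance; Otsu threshold on the luminance
#' histogram; morphological opening (3 x 3) to suppress salt noise;
#' largest 8-connected foreground component; hole filling, so dark wound
#' regions enclosed by skin stay part of the foot and the downstream
#' ulcer/foot area ratio has a well-defined denominator.  Sticker pixels
#' inside the silhouette count as foot.
#'
#' @param image Integer `H x W x 3` array, values 0--255.
#' @param opening_iterations Opening passes before component selection
#'   (default 1; 0 disables).
#' @param min_image_fraction Minimum fraction of the image the largest
#'   component must cover (default 0.02); below it the foot is declared
#'   absent.
#' @return Object of class `"foot_segmentation"`: `foot_mask` (logical
#'   matrix, one filled component), `foot_area_px`, `foot_centroid_px`.
#' @export
segment_foot <- function(image, opening_iterations = 1L,
                         min_image_fraction = 0.02) {
  lum <- luminance(image)
  if (max(lum) - min(lum) < 1)
    um_stop("um_no_foot", "image has no luminance contrast")
  t <- otsu_threshold(lum)
  fg <- lum > t
  if (opening_iterations > 0) fg <- binary_opening(fg, opening_iterations)
  if (!any(fg))
    um_stop("um_no_foot", "no foreground pixels above the Otsu threshold")
  comp <- largest_component(fg)
  if (sum(comp) < min_image_fraction * length(comp))
    um_stop("um_no_foot",
            sprintf("largest bright component covers %.2f%% of the image (< %.0f%%)",
                    100 * sum(comp) / length(comp), 100 * min_image_fraction))
  mask <- fill_holes(comp)
  out <- list(foot_mask = mask,
              foot_area_px = sum(mask),
              foot_centroid_px = mask_centroid(mask))
  class(out) <- "foot_segmentation"
  out
}

#' @export
print.foot_segmentation <- function(x, ...) {
  cat(sprintf("Foot segmentation: %d px, centroid (%.1f, %.1f)\n",
              x$foot_area_px, x$foot_centroid_px[1], x$foot_centroid_px[2]))
  invisible(x)
}
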