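# Scribble-seeded ulcer segmentation.  The user roughly draws one stroke
# around the ulcer on intact skin and one stroke inside it; the strokes
# seed a marker-based watershed on the luminance-gradient relief, and the
# resulting ulcer boundary is drawn back on the photo as a green line.

SKIN_LABEL <- 1L
ULCER_LABEL <- 2L

#' Scribble strokes labelling skin and ulcer
#'
#' @param skin_stroke Integer `n x 2` matrix of ordered `(row, col)`
#'   points drawn around the ulcer on intact skin.
#' @param ulcer_stroke Integer `m x 2` matrix of ordered `(row, col)`
#'   points drawn inside the ulcer.
#' @return Object of class `"scribble_set"`.
#' @export
scribble_set <- function(skin_stroke, ulcer_stroke) {
  skin <- round(as.matrix(skin_stroke))
  ulcer <- round(as.matrix(ulcer_stroke))
  stopifnot(ncol(skin) == 2L, ncol(ulcer) == 2L,
            nrow(skin) >= 1L, nrow(ulcer) >= 1L)
  out <- list(skin_stroke = skin, ulcer_stroke = ulcer)
  class(out) <- "scribble_set"
  out
}

#' Read / write scribbles as JSON
#'
#' Format: `{"skin_stroke": [[r, c], ...], "ulcer_stroke": [[r, c], ...]}`
#' with 1-based `(row, col)` coordinates.
#'
#' @param path JSON file path.
#' @param scribbles A [scribble_set()].
#' @return `read_scribbles`: a `"scribble_set"`.
#' @export
read_scribbles <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scribble_set(x$skin_stroke, x$ulcer_stroke)
}

#' @rdname read_scribbles
#' @export
write_scribbles <- function(scribbles, path) {
  jsonlite::write_json(list(skin_stroke = unname(scribbles$skin_stroke),
                            ulcer_stroke = unname(scribbles$ulcer_stroke)),
                       path, digits = NA)
  invisible(path)
}

# Integer Bresenham line between two (row, col) points, inclusive.
bresenham <- function(p, q) {
  r0 <- p[1]; c0 <- p[2]; r1 <- q[1]; c1 <- q[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 >= -dr) { err <- err - dr; c <- c + sc }
    if (e2 <= dc) { err <- err + dc; r <- r + sr }
  }
  out
}

rasterize_stroke <- function(points, height, width) {
  pts <- points
  if (any(pts[, 1] < 1 | pts[, 1] > height | pts[, 2] < 1 | pts[, 2] > width))
    um_stop("um_out_of_bounds", "scribble point outside the image")
  mask <- matrix(FALSE, height, width)
  if (nrow(pts) == 1L) {
    mask[pts[1, 1], pts[1, 2]] <- TRUE
    return(mask)
  }
  for (i in seq_len(nrow(pts) - 1L))
    mask[bresenham(pts[i, ], pts[i + 1L, ])] <- TRUE
  mask
}

#' Rasterize scribbles into a watershed marker grid
#'
#' Consecutive stroke points are connected with Bresenham line pixels;
#' skin pixels get label 1 and ulcer pixels label 2.  A pixel touched by
#' both strokes is an error.
#'
#' @param scribbles A [scribble_set()].
#' @param height,width Image dimensions.
#' @return Integer `height x width` marker grid: 0 unlabeled, 1 skin,
#'   2 ulcer.
#' @export
rasterize_scribbles <- function(scribbles, height, width) {
  stopifnot(inherits(scribbles, "scribble_set"))
  skin <- rasterize_stroke(scribbles$skin_stroke, height, width)
  ulcer <- rasterize_stroke(scribbles$ulcer_stroke, height, width)
  if (any(skin & ulcer))
    um_stop("um_overlapping_scribbles",
            "skin and ulcer scribbles touch the same pixel")
  markers <- matrix(0L, height, width)
  markers[skin] <- SKIN_LABEL
  markers[ulcer] <- ULCER_LABEL
  markers
}

#' Luminance-gradient relief for the watershed
#'
#' Per-pixel maximum absolute luminance difference to the pixel's
#' 4-neighbors.
#'
#' @param image Integer `H x W x 3` array.
#' @return Numeric `H x W` relief matrix.
#' @export
luminance_relief <- function(image) cpp_relief(luminance(image))

#' Marker-seeded watershed segmentation of the ulcer
#'
#' Priority-flood watershed on the luminance-gradient relief: a priority
#' queue is initialized with all unlabeled 4-neighbors of marker pixels
#' (raster scan order; neighbors up, down, left, right); the lowest-relief
#' pixel is popped (FIFO among equal relief, by insertion order), takes
#' the label of the pixel that enqueued it, and enqueues its own unlabeled
#' neighbors.  Every pixel ends up labeled; no ridge label is kept.
#' Pixels outside `foot_mask` are pre-assigned the skin label so the ulcer
#' cannot leak into the background.  Marker pixels always keep their
#' seeded label.
#'
#' @param image Integer `H x W x 3` array.
#' @param markers Integer marker grid from [rasterize_scribbles()].
#' @param foot_mask Logical foot silhouette from [segment_foot()], or
#'   `NULL` to flood the whole frame.
#' @return Object of class `"ulcer_segmentation"`: `ulcer_mask`,
#'   `boundary_contour` (closed `(row, col)` contour of the largest ulcer
#'   component), `n_ulcer_px`, `label_grid`.
#' @export
watershed_segment <- function(image, markers, foot_mask = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  stopifnot(nrow(markers) == H, ncol(markers) == W)
  m <- markers
  if (!is.null(foot_mask)) {
    stopifnot(nrow(foot_mask) == H, ncol(foot_mask) == W)
    m[!foot_mask & m == 0L] <- SKIN_LABEL
  }
  if (!any(m == SKIN_LABEL) || !any(m == ULCER_LABEL))
    um_stop("um_missing_marker",
            "markers must contain both a skin and an ulcer label")
  labels <- cpp_watershed(luminance_relief(image), m)
  ulcer_mask <- labels == ULCER_LABEL
  contour <- if (any(ulcer_mask))
    cpp_moore_boundary(largest_component(ulcer_mask))
  else matrix(integer(0), 0L, 2L)
  out <- list(ulcer_mask = ulcer_mask,
              boundary_contour = contour,
              n_ulcer_px = sum(ulcer_mask),
              label_grid = labels)
  class(out) <- "ulcer_segmentation"
  out
}

#' @export
print.ulcer_segmentation <- function(x, ...) {
  cat(sprintf("Ulcer segmentation: %d px, boundary of %d points\n",
              x$n_ulcer_px, max(0L, nrow(x$boundary_contour) - 1L)))
  invisible(x)
}

#' Trace the outer boundary of a single-component mask
#'
#' Moore-neighbor trace, clockwise, starting from the
#' topmost-then-leftmost boundary pixel; the contour is closed (first
#' point repeated last).
#'
#' @param mask Logical matrix with exactly one 8-connected component.
#' @return Integer `k x 2` matrix of `(row, col)` contour points.
#' @export
extract_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) um_stop("um_empty_mask", "cannot trace an empty mask")
  if (max(cpp_label_components(mask, 8L)) > 1L)
    um_stop("um_multiple_components",
            "mask has more than one connected component")
  cpp_moore_boundary(mask)
}

#' Draw a contour on an image as a green line
#'
#' Returns a copy of the image with every contour pixel set to pure green
#' `(0, 255, 0)`; the input is untouched and the operation is idempotent.
#'
#' @param image Integer `H x W x 3` array.
#' @param contour Integer `k x 2` matrix of `(row, col)` points.
#' @return New image array.
#' @export
overlay_contour <- function(image, contour) {
  out <- image
  if (is.null(contour) || nrow(contour) == 0L) return(out)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (any(contour[, 1] < 1 | contour[, 1] > H |
          contour[, 2] < 1 | contour[, 2] > W))
    um_stop("um_out_of_bounds", "contour point outside the image")
  out[cbind(contour[, 1], contour[, 2], 1L)] <- 0L
  out[cbind(contour[, 1], contour[, 2], 2L)] <- 255L
  out[cbind(contour[, 1], contour[, 2], 3L)] <- 0L
  out
}
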