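#' Luminance of an RGB image
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B` on 8-bit channel values.
#'
#' @param image Integer array `H x W x 3`, channel values 0--255.
#' @return Numeric `H x W` matrix of luminance values in 0--255.
#' @export
luminance <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  # integer-weighted form: exact for gray pixels, so relief ties between
  # equal-luminance pixels are exact and the watershed FIFO rule is stable
  lum <- (299 * image[, , 1] + 587 * image[, , 2] + 114 * image[, , 3]) / 1000
  dim(lum) <- dim(image)[1:2]    # keep matrix shape for 1-row/1-col images
  lum
}

#' Otsu threshold of a luminance matrix
#'
#' Maximizes the between-class variance of the 256-bin histogram of the
#' rounded luminance values.  Ties are broken toward the smallest
#' threshold so the result is deterministic.
#'
#' @param lum Numeric matrix of luminance values in 0--255.
#' @return Integer threshold `t` in 0--255; foreground is `lum > t`.
#' @export
otsu_threshold <- function(lum) {
  v <- as.integer(round(lum))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  p <- h / n
  omega <- cumsum(p)                     # class-0 weight for t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  which.max(sigma_b2) - 1L               # smallest argmax
}

#' Label connected components of a binary mask
#'
#' Components are numbered 1, 2, ... in raster-scan order of their first
#' pixel, so labeling is deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  cpp_label_components(mask, as.integer(connectivity))
}

#' Fill enclosed holes in a binary mask
#'
#' Background pixels not 4-connected to the image border are switched to
#' foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_fill_holes(mask)
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(mask, dr, dc) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- mask[rs - dr, cs - dc, drop = FALSE]
  out
}

binary_erode3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mask(mask, dr, dc)
  }
  out
}

binary_dilate3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mask(mask, dr, dc)
  }
  out
}

#' Morphological opening with a 3 x 3 square structuring element
#'
#' Erosion followed by dilation; suppresses isolated salt noise before
#' component selection.  Pixels outside the image count as background.
#'
#' @param mask Logical matrix.
#' @param iterations Number of opening passes (0 disables).
#' @return Logical matrix.
#' @export
binary_opening <- function(mask, iterations = 1L) {
  out <- mask
  for (i in seq_len(iterations)) out <- binary_dilate3(binary_erode3(out))
  out
}

#' Rasterize a polygon by the pixel-center even-odd rule
#'
#' A pixel `(r, c)` belongs to the polygon iff its center (the integer
#' point) is inside by the even-odd rule.  Place vertices at half-integer
#' coordinates for exact pixel counts on axis-aligned shapes.
#'
#' @param vertices Numeric `n x 2` matrix of `(row, col)` vertices,
#'   in order, not necessarily closed.
#' @param height,width Image dimensions.
#' @return Logical `height x width` mask.
#' @export
rasterize_polygon <- function(vertices, height, width) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L, nrow(v) >= 3L)
  mask <- matrix(FALSE, height, width)
  y1 <- v[, 1]; x1 <- v[, 2]
  y2 <- c(v[-1, 1], v[1, 1]); x2 <- c(v[-1, 2], v[1, 2])
  keep <- y1 != y2                       # horizontal edges never cross
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  r_lo <- max(1L, ceiling(min(v[, 1]))); r_hi <- min(height, floor(max(v[, 1])))
  if (r_lo > r_hi) return(mask)
  for (r in r_lo:r_hi) {
    # half-open rule [min(y), max(y)): deterministic at shared vertices
    crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(crosses)) next
    xi <- x1[crosses] + (r - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      c_lo <- max(1L, ceiling(xi[k]))
      c_hi <- min(width, floor(xi[k + 1]))
      if (xi[k + 1] == floor(xi[k + 1])) c_hi <- min(width, xi[k + 1] - 1L)
      if (c_lo <= c_hi) mask[r, c_lo:c_hi] <- TRUE
    }
  }
  mask
}

#' Signed analytic area of a polygon (shoelace), in squared pixels
#'
#' @param vertices Numeric `n x 2` matrix of `(row, col)` vertices.
#' @return Positive area in px^2, independent of orientation.
#' @export
polygon_area_px2 <- function(vertices) {
  v <- as.matrix(vertices)
  y <- v[, 1]; x <- v[, 2]
  yn <- c(y[-1], y[1]); xn <- c(x[-1], x[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Elliptical and circular disc masks by the pixel-center rule.
ellipse_mask <- function(center, semi_axes, height, width) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - center[1]) / semi_axes[1])^2 + ((c - center[2]) / semi_axes[2])^2 <= 1
}

disc_mask <- function(center, radius, height, width) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# Largest 8-connected component of a mask (first in raster order on ties).
largest_component <- function(mask) {
  lab <- cpp_label_components(mask, 8L)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(areas)
}

mask_centroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(mean(w[, 1]), mean(w[, 2]))
}

#' Read / write 8-bit images and masks as PNG
#'
#' Images are `H x W x 3` integer arrays (0--255); masks are logical
#' matrices stored as single-channel 0/255 PNG.
#'
#' @param path File path.
#' @param image Integer `H x W x 3` array.
#' @param mask Logical matrix.
#' @return `read_image`: integer array; `read_mask`: logical matrix.
#' @name image_io
NULL

#' @rdname image_io
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  a <- array(as.integer(round(x * 255)), dim = dim(x))
  a
}

#' @rdname image_io
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' @rdname image_io
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

# Run code with a private RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
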