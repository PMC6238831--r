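# Synthetic foot-photo scenes with exact ground truth.  The scenes emulate
# the flash-lit capture conditions the pipeline assumes: a bright plantar
# foot on a dark background, a darker ulcer region on the sole, and one
# solid green circular sticker of known 1-cm physical diameter providing
# the pixel-to-centimetre scale.

#' Default fixture palette
#'
#' Fixture colors chosen so the sticker satisfies the green-dominance rule
#' of [classify_green()] while skin, ulcer and background do not.
#' @return Named list of RGB triples.
#' @export
fixture_colors <- function() {
  list(skin = c(210L, 170L, 140L),
       ulcer = c(150L, 40L, 40L),
       sticker = c(30L, 200L, 60L),
       background = c(15L, 15L, 15L))
}

#' Default ulcer outline polygon
#'
#' Closed star-convex polygon with a gently wobbled radius profile,
#' deterministic in its arguments; used as the default ulcer shape and as
#' a convenient building block for custom scenes.
#'
#' @param center `(row, col)` centroid in pixels.
#' @param mean_radius Mean vertex radius in pixels.
#' @param n_vertices Number of vertices.
#' @return Numeric `n_vertices x 2` matrix of `(row, col)` vertices.
#' @export
default_ulcer_polygon <- function(center = c(120, 100), mean_radius = 20,
                                  n_vertices = 8) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  wobble <- 1 + 0.15 * sin(3 * th + 0.7)   # fixed, deterministic shape
  cbind(center[1] + mean_radius * wobble * sin(th),
        center[2] + mean_radius * wobble * cos(th))
}

#' Scene parameters for the synthetic foot-photo generator
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param foot_semi_axes_px Ellipse semi-axes `(a, b)` along rows and
#'   columns, in pixels.
#' @param foot_center_px Ellipse center `(row, col)`.
#' @param foot_luminance,background_luminance 8-bit luminance levels; the
#'   flash-contrast model requires a difference of at least 80.
#' @param ulcer_vertices_px Ordered `(row, col)` polygon vertices, strictly
#'   inside the foot ellipse.
#' @param ulcer_color,sticker_color RGB triples; the sticker color must be
#'   green-dominant in the sense of [classify_green()].
#' @param sticker_center_px Sticker disc center `(row, col)`, on intact
#'   skin inside the foot and disjoint from the ulcer.
#' @param sticker_radius_px Sticker disc radius in pixels; the physical
#'   diameter is fixed at 1 cm, so `pixels_per_cm = 2 * sticker_radius_px`.
#' @param noise_sigma Standard deviation of additive per-pixel Gaussian
#'   noise (8-bit units), applied after ground-truth masks are captured.
#' @param illumination_gradient Linear luminance slope per row, centered on
#'   the middle row (0 disables).
#' @param seed Integer seed driving all randomness in the scene.
#' @return List of class `"scene_params"`.
#' @export
scene_params <- function(image_height_px = 240L,
                         image_width_px = 320L,
                         foot_semi_axes_px = c(100, 140),
                         foot_center_px = c(120.5, 160.5),
                         foot_luminance = 200L,
                         background_luminance = 15L,
                         ulcer_vertices_px = default_ulcer_polygon(),
                         ulcer_color = fixture_colors()$ulcer,
                         sticker_center_px = c(120.5, 230.5),
                         sticker_radius_px = 20,
                         sticker_color = fixture_colors()$sticker,
                         noise_sigma = 0,
                         illumination_gradient = 0,
                         seed = 1L) {
  p <- list(image_height_px = as.integer(image_height_px),
            image_width_px = as.integer(image_width_px),
            foot_semi_axes_px = as.numeric(foot_semi_axes_px),
            foot_center_px = as.numeric(foot_center_px),
            foot_luminance = as.numeric(foot_luminance),
            background_luminance = as.numeric(background_luminance),
            ulcer_vertices_px = as.matrix(ulcer_vertices_px),
            ulcer_color = as.numeric(ulcer_color),
            sticker_center_px = as.numeric(sticker_center_px),
            sticker_radius_px = as.numeric(sticker_radius_px),
            sticker_color = as.numeric(sticker_color),
            noise_sigma = as.numeric(noise_sigma),
            illumination_gradient = as.numeric(illumination_gradient),
            seed = as.integer(seed))
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p, require_sticker = TRUE,
                                  require_ulcer = TRUE) {
  H <- p$image_height_px; W <- p$image_width_px
  a <- p$foot_semi_axes_px[1]; b <- p$foot_semi_axes_px[2]
  ctr <- p$foot_center_px
  if (ctr[1] - a < 1 || ctr[1] + a > H || ctr[2] - b < 1 || ctr[2] + b > W)
    um_stop("um_invalid_geometry", "foot ellipse extends outside the image")
  if (p$foot_luminance - p$background_luminance < 80)
    um_stop("um_invalid_geometry",
            "foot/background luminance contrast below 80 (flash model)")
  inside_foot <- function(rc)
    ((rc[, 1] - ctr[1]) / a)^2 + ((rc[, 2] - ctr[2]) / b)^2 < 1
  if (require_ulcer) {
    v <- p$ulcer_vertices_px
    if (!all(inside_foot(v)))
      um_stop("um_invalid_geometry", "ulcer polygon not strictly inside foot")
  }
  if (require_sticker) {
    s <- p$sticker_center_px; r <- p$sticker_radius_px
    extremes <- rbind(s + c(r, 0), s - c(r, 0), s + c(0, r), s - c(0, r))
    if (!all(inside_foot(extremes)))
      um_stop("um_invalid_geometry", "sticker disc not inside foot ellipse")
    g <- p$sticker_color
    if (!(g[2] > 1.3 * g[1] && g[2] > 1.3 * g[3] && g[2] >= 60))
      um_stop("um_invalid_geometry", "sticker color is not green-dominant")
  }
  invisible(TRUE)
}

# Paint RGB `color` on all TRUE pixels of `mask` in image array `img`.
paint <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Render a synthetic foot scene with exact ground truth
#'
#' Renders background, foot ellipse, ulcer polygon and sticker disc, then
#' applies the optional linear row-wise illumination ramp and per-pixel
#' Gaussian noise (clipped to 0--255).  Masks are captured before ramp and
#' noise, so they are exact.  The skin color is the fixture skin tone
#' rescaled so its luminance equals `foot_luminance`.
#'
#' @param params A [scene_params()] object.
#' @param with_ulcer,with_sticker Disable to render control scenes (e.g.
#'   a sticker-free scene for failure-path tests).
#' @return List of class `"scene_truth"`: `image`, `foot_mask`,
#'   `ulcer_mask`, `sticker_mask`, `true_pixels_per_cm`,
#'   `true_ulcer_area_cm2` (rasterized-mask area over scale squared),
#'   `analytic_ulcer_area_cm2` (shoelace polygon area over scale squared),
#'   `true_foot_area_px`, and `params`.
#' @export
generate_scene <- function(params, with_ulcer = TRUE, with_sticker = TRUE) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  validate_scene_params(p, require_sticker = with_sticker,
                        require_ulcer = with_ulcer)
  H <- p$image_height_px; W <- p$image_width_px

  foot_mask <- ellipse_mask(p$foot_center_px, p$foot_semi_axes_px, H, W)
  ulcer_mask <- if (with_ulcer)
    rasterize_polygon(p$ulcer_vertices_px, H, W) else matrix(FALSE, H, W)
  sticker_mask <- if (with_sticker)
    disc_mask(p$sticker_center_px, p$sticker_radius_px, H, W)
  else matrix(FALSE, H, W)
  if (any(sticker_mask & ulcer_mask))
    um_stop("um_invalid_geometry", "sticker disc overlaps the ulcer polygon")

  cols <- fixture_colors()
  skin_rgb <- cols$skin * p$foot_luminance / sum(cols$skin * c(0.299, 0.587, 0.114))
  img <- array(0, dim = c(H, W, 3))
  img <- paint(img, !foot_mask, rep(p$background_luminance, 3))
  img <- paint(img, foot_mask, skin_rgb)
  img <- paint(img, ulcer_mask, p$ulcer_color)
  img <- paint(img, sticker_mask, p$sticker_color)

  if (p$illumination_gradient != 0) {
    ramp <- p$illumination_gradient * (seq_len(H) - (H + 1) / 2)
    img <- img + array(ramp, dim = c(H, W, 3))
  }
  if (p$noise_sigma > 0)
    img <- with_seed(p$seed,
                     img + array(rnorm(H * W * 3, 0, p$noise_sigma),
                                 dim = c(H, W, 3)))
  img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = c(H, W, 3))

  ppc <- 2 * p$sticker_radius_px      # sticker physical diameter is 1 cm
  out <- list(image = img,
              foot_mask = foot_mask,
              ulcer_mask = ulcer_mask,
              sticker_mask = sticker_mask,
              true_pixels_per_cm = ppc,
              true_ulcer_area_cm2 = sum(ulcer_mask) / ppc^2,
              analytic_ulcer_area_cm2 =
                polygon_area_px2(p$ulcer_vertices_px) / ppc^2,
              true_foot_area_px = sum(foot_mask),
              params = p)
  class(out) <- "scene_truth"
  out
}

#' @export
print.scene_truth <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Synthetic foot scene %d x %d px\n", d[1], d[2]))
  cat(sprintf("  foot area: %d px; ulcer area: %d px (%.4f cm2)\n",
              x$true_foot_area_px, sum(x$ulcer_mask), x$true_ulcer_area_cm2))
  cat(sprintf("  scale: %.1f px/cm (sticker radius %.1f px)\n",
              x$true_pixels_per_cm, x$params$sticker_radius_px))
  invisible(x)
}

# Scale a polygon about its centroid so its shoelace area equals
# `target_px2`.
scale_polygon_to_area <- function(vertices, target_px2) {
  v <- as.matrix(vertices)
  ctr <- colMeans(v)
  s <- sqrt(target_px2 / polygon_area_px2(v))
  t(ctr + s * (t(v) - ctr))
}

#' Generate a longitudinal healing series of scenes
#'
#' Produces `n_weeks + 1` scenes at day offsets 0, 7, ..., 7 n_weeks.  The
#' ulcer polygon of week `w` is the base polygon scaled about its centroid
#' so the analytic ulcer area equals
#' `initial_area_cm2 * (1 - weekly_reduction_fraction)^w`, a geometric
#' healing trajectory.
#'
#' @param initial_area_cm2 Baseline analytic ulcer area, cm^2.
#' @param weekly_reduction_fraction Fractional area reduction per week,
#'   in `[0, 1)`.
#' @param n_weeks Number of weeks (>= 1).
#' @param base_params Scene parameters providing geometry, colors, noise.
#' @param seed Integer; week `w` uses scene seed `seed + w`.
#' @return List of entries `list(day_offset, scene)`.
#' @export
generate_healing_series <- function(initial_area_cm2,
                                    weekly_reduction_fraction,
                                    n_weeks,
                                    base_params = scene_params(),
                                    seed = 1L) {
  stopifnot(n_weeks >= 1, initial_area_cm2 > 0,
            weekly_reduction_fraction >= 0, weekly_reduction_fraction < 1)
  ppc <- 2 * base_params$sticker_radius_px
  lapply(0:n_weeks, function(w) {
    target_cm2 <- initial_area_cm2 * (1 - weekly_reduction_fraction)^w
    verts <- scale_polygon_to_area(base_params$ulcer_vertices_px,
                                   target_cm2 * ppc^2)
    p <- base_params
    p$ulcer_vertices_px <- verts
    p$seed <- as.integer(seed + w)
    list(day_offset = 7L * w, scene = generate_scene(p))
  })
}

#' Generate a capture-sweep frame sequence under a pinhole camera model
#'
#' One frame per height: the phone lies on the floor, camera facing up,
#' and the foot hovers at `height_cm` above it.  Apparent foot size scales
#' as `focal_px / height_cm`, so the silhouette area is strictly
#' decreasing in height.  Frames contain the foot silhouette only (no
#' ulcer or sticker): capture guidance uses the silhouette alone.
#'
#' @param heights_cm Strictly positive heights, one per frame.
#' @param foot_true_length_cm Physical foot length (major axis), cm.
#' @param focal_px Pinhole focal constant in pixels: an object of size
#'   `s` cm at distance `h` cm projects to `focal_px * s / h` pixels.
#' @param base_params Scene parameters for image size, colors, aspect.
#' @param center_offset_px Optional `(d_row, d_col)` shift of the foot
#'   center from the image center, applied to every frame.
#' @return List of `H x W x 3` integer image arrays.
#' @export
generate_capture_sweep <- function(heights_cm,
                                   foot_true_length_cm = 24,
                                   focal_px = 220,
                                   base_params = scene_params(),
                                   center_offset_px = c(0, 0)) {
  stopifnot(all(heights_cm > 0))
  H <- base_params$image_height_px; W <- base_params$image_width_px
  aspect <- base_params$foot_semi_axes_px /
    max(base_params$foot_semi_axes_px)
  ctr <- c((H + 1) / 2 + center_offset_px[1],
           (W + 1) / 2 + center_offset_px[2])
  lapply(heights_cm, function(h) {
    semi_major <- focal_px * (foot_true_length_cm / 2) / h
    semi <- semi_major * aspect
    p <- base_params
    p$foot_center_px <- ctr
    p$foot_semi_axes_px <- semi
    if (ctr[1] - semi[1] < 1 || ctr[1] + semi[1] > H ||
        ctr[2] - semi[2] < 1 || ctr[2] + semi[2] > W)
      um_stop("um_invalid_geometry",
              sprintf("projected foot at height %.1f cm exceeds image bounds", h))
    generate_scene(p, with_ulcer = FALSE, with_sticker = FALSE)$image
  })
}

#' Derive correct scribbles from a scene's ground truth
#'
#' Emulates a user who draws one stroke inside the ulcer and one stroke
#' around it on intact skin: the ulcer stroke is a short segment through
#' the ulcer-mask pixel nearest the mask centroid; the skin stroke is the
#' outer boundary of the ulcer mask dilated by `margin` pixels, clipped to
#' the foot.
#'
#' @param truth A `"scene_truth"` object with a nonempty ulcer mask.
#' @param margin Dilation margin in pixels between ulcer boundary and the
#'   skin stroke.
#' @return A [scribble_set()].
#' @export
truth_scribbles <- function(truth, margin = 5L) {
  um <- truth$ulcer_mask
  if (!any(um)) um_stop("um_empty_mask", "scene has no ulcer")
  w <- which(um, arr.ind = TRUE)
  ctr <- colMeans(w)
  nearest <- w[which.min((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2), ]
  # short horizontal segment through the interior point, clipped to ulcer
  seg_cols <- nearest[2] + (-2:2)
  seg_cols <- seg_cols[seg_cols >= 1 & seg_cols <= ncol(um)]
  seg_cols <- seg_cols[um[nearest[1], seg_cols]]
  ulcer_stroke <- cbind(nearest[1], seg_cols)
  if (nrow(ulcer_stroke) == 0) ulcer_stroke <- rbind(nearest)

  ring <- um
  for (i in seq_len(margin)) ring <- binary_dilate3(ring)
  ring <- ring & truth$foot_mask
  contour <- extract_boundary(largest_component(ring))
  skin_pts <- contour[!um[contour] & truth$foot_mask[contour], , drop = FALSE]
  scribble_set(skin_stroke = skin_pts, ulcer_stroke = ulcer_stroke)
}

#' Write a scene and its ground truth to disk
#'
#' Writes `image.png`, `foot_mask.png`, `ulcer_mask.png`,
#' `sticker_mask.png` (0/255 single-channel) and `truth.json` (parameters
#' and derived truth values) into `dir`.
#'
#' @param truth A `"scene_truth"` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(truth$image, file.path(dir, "image.png"))
  write_mask(truth$foot_mask, file.path(dir, "foot_mask.png"))
  write_mask(truth$ulcer_mask, file.path(dir, "ulcer_mask.png"))
  write_mask(truth$sticker_mask, file.path(dir, "sticker_mask.png"))
  p <- truth$params
  p$ulcer_vertices_px <- apply(p$ulcer_vertices_px, 1, identity,
                               simplify = FALSE)
  info <- list(params = unclass(p),
               true_pixels_per_cm = truth$true_pixels_per_cm,
               true_ulcer_area_cm2 = truth$true_ulcer_area_cm2,
               analytic_ulcer_area_cm2 = truth$analytic_ulcer_area_cm2,
               true_foot_area_px = truth$true_foot_area_px)
  jsonlite::write_json(info, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
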