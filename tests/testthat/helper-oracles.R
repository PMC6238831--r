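# Independent brute-force oracles and small fixture helpers.  The oracles
# re-state the algorithm contracts literally (linear scans, no heaps) so
# they share no code with the package implementation.

iou <- function(a, b) sum(a & b) / sum(a | b)

# Literal priority-flood watershed: the queue is a list scanned in full
# for the minimum (relief, insertion-order) entry at every pop.
oracle_watershed <- function(relief, markers) {
  H <- nrow(relief); W <- ncol(relief)
  labels <- markers
  queue <- list()
  counter <- 0L
  push <- function(r, c, lab) {
    counter <<- counter + 1L
    queue[[length(queue) + 1L]] <<- list(rel = relief[r, c], ord = counter,
                                         r = r, c = c, lab = lab)
  }
  neighbors <- function(r, c)
    list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (labels[r, c] <= 0L) next
    for (n in neighbors(r, c))
      if (n[1] >= 1 && n[1] <= H && n[2] >= 1 && n[2] <= W &&
          labels[n[1], n[2]] == 0L)
        push(n[1], n[2], labels[r, c])
  }
  while (length(queue) > 0L) {
    rels <- vapply(queue, `[[`, numeric(1), "rel")
    ords <- vapply(queue, `[[`, numeric(1), "ord")
    best <- which(rels == min(rels))
    best <- best[which.min(ords[best])]
    e <- queue[[best]]
    queue[[best]] <- NULL
    if (labels[e$r, e$c] != 0L) next
    labels[e$r, e$c] <- e$lab
    for (n in neighbors(e$r, e$c))
      if (n[1] >= 1 && n[1] <= H && n[2] >= 1 && n[2] <= W &&
          labels[n[1], n[2]] == 0L)
        push(n[1], n[2], e$lab)
  }
  labels
}

# Literal 4-neighbor maximum-absolute-difference relief.
oracle_relief <- function(lum) {
  H <- nrow(lum); W <- ncol(lum)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    m <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
        m <- max(m, abs(lum[r, c] - lum[rr, cc]))
    }
    out[r, c] <- m
  }
  out
}

# Grayscale RGB image from a luminance matrix (equal channels, so the
# Rec. 601 luminance equals the matrix).
gray_image <- function(lum) {
  array(as.integer(round(lum)), dim = c(nrow(lum), ncol(lum), 3L))
}

# Small scene for fast unit tests: 120 x 160 px, 20 px/cm.
small_scene_params <- function(seed = 1L, ...) {
  scene_params(image_height_px = 120L, image_width_px = 160L,
               foot_semi_axes_px = c(50, 70),
               foot_center_px = c(60.5, 80.5),
               ulcer_vertices_px = default_ulcer_polygon(center = c(60, 50),
                                                         mean_radius = 12),
               sticker_center_px = c(60.5, 115.5),
               sticker_radius_px = 10,
               seed = seed, ...)
}

# Randomized full-size scene parameters used by the property-style and
# acceptance tests: geometry varies with the seed, conditions (contrast,
# colors, noise level) stay at the study defaults.
random_scene_params <- function(seed, sticker_radius_px = NULL,
                                noise_sigma = 0) {
  pars <- with_seed_local(seed, {
    list(radius = if (is.null(sticker_radius_px))
           runif(1, 15, 30) else sticker_radius_px,
         ulcer_r = runif(1, 14, 26),
         ulcer_ctr = c(runif(1, 105, 135), runif(1, 85, 115)),
         n_vert = sample(6:10, 1))
  })
  scene_params(
    ulcer_vertices_px = default_ulcer_polygon(center = pars$ulcer_ctr,
                                              mean_radius = pars$ulcer_r,
                                              n_vertices = pars$n_vert),
    sticker_radius_px = pars$radius,
    noise_sigma = noise_sigma,
    seed = seed)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Jitter scribble points by +/- amount px (deterministic in seed).
jitter_scribbles <- function(scr, amount = 2L, seed = 1L) {
  with_seed_local(seed, {
    j <- function(m) m + matrix(sample(-amount:amount, length(m), TRUE),
                                nrow(m), ncol(m))
    scribble_set(j(scr$skin_stroke), j(scr$ulcer_stroke))
  })
}
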