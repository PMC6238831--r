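test_that("scribbles rasterize to Bresenham-connected marker lines", {
  scr <- scribble_set(skin_stroke = rbind(c(1, 1), c(1, 3)),
                      ulcer_stroke = rbind(c(5, 5)))
  m <- rasterize_scribbles(scr, 5L, 5L)
  expect_true(all(m[cbind(1, 1:3)] == 1L))
  expect_equal(m[5, 5], 2L)
  expect_equal(sum(m == 2L), 1L)
  expect_equal(sum(m != 0L), 4L)
  # diagonal stroke is 8-connected
  d <- rasterize_scribbles(scribble_set(rbind(c(1, 1), c(4, 4)),
                                        rbind(c(6, 1))), 6L, 6L)
  expect_equal(sum(d == 1L), 4L)
  expect_true(all(d[cbind(1:4, 1:4)] == 1L))
})

test_that("overlapping and out-of-bounds scribbles are rejected", {
  expect_error(
    rasterize_scribbles(scribble_set(rbind(c(2, 1), c(2, 4)),
                                     rbind(c(2, 2))), 5L, 5L),
    class = "um_overlapping_scribbles")
  expect_error(
    rasterize_scribbles(scribble_set(rbind(c(1, 1)), rbind(c(9, 2))), 5L, 5L),
    class = "um_out_of_bounds")
})

test_that("relief is the 4-neighbor maximum absolute luminance difference", {
  for (seed in 1:5) {
    lum <- with_seed_local(seed, matrix(sample(0:255, 48, TRUE), 6, 8))
    expect_equal(luminance_relief(gray_image(lum)), oracle_relief(lum))
  }
})

test_that("the 1 x 5 ridge row floods exactly as worked out by hand", {
  img <- gray_image(matrix(c(200, 200, 80, 80, 80), 1, 5))
  expect_equal(luminance_relief(img)[1, ], c(0, 120, 120, 0, 0))
  markers <- matrix(0L, 1, 5)
  markers[1, 1] <- 1L; markers[1, 5] <- 2L
  seg <- watershed_segment(img, markers)
  expect_equal(seg$ulcer_mask[1, ], c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(seg$label_grid, oracle_watershed(luminance_relief(img),
                                                    markers))
})

test_that("priority-flood labeling equals the brute-force oracle on random grids", {
  for (seed in 1:30) {
    vals <- with_seed_local(seed, {
      list(lum = matrix(sample(0:255, 64, TRUE), 8, 8),
           marks = sample(64, 2))
    })
    markers <- matrix(0L, 8, 8)
    markers[vals$marks[1]] <- 1L
    markers[vals$marks[2]] <- 2L
    relief <- oracle_relief(vals$lum)
    got <- watershed_segment(gray_image(vals$lum), markers)$label_grid
    expect_identical(got, oracle_watershed(relief, markers))
  }
})

test_that("the flood partitions the frame and markers keep their labels", {
  # uniform image, markers at opposite corners: every pixel gets a label
  img <- gray_image(matrix(120, 12, 12))
  markers <- matrix(0L, 12, 12)
  markers[1, 1] <- 1L; markers[12, 12] <- 2L
  seg <- watershed_segment(img, markers)
  expect_true(all(seg$label_grid %in% 1:2))
  expect_equal(sum(seg$label_grid == 1L) + sum(seg$label_grid == 2L), 144L)
  expect_equal(seg$label_grid[1, 1], 1L)
  expect_equal(seg$label_grid[12, 12], 2L)
  expect_error(watershed_segment(img, matrix(1L, 12, 12)),
               class = "um_missing_marker")
})

test_that("pixels outside the foot are forced to skin before flooding", {
  tr <- generate_scene(small_scene_params())
  scr <- truth_scribbles(tr)
  m <- rasterize_scribbles(scr, 120L, 160L)
  seg <- watershed_segment(tr$image, m, tr$foot_mask)
  expect_false(any(seg$ulcer_mask & !tr$foot_mask))
})

test_that("watershed recovers fixture ulcers from correct scribbles", {
  for (seed in 1:8) {
    tr <- generate_scene(random_scene_params(seed))
    foot <- segment_foot(tr$image)
    m <- rasterize_scribbles(truth_scribbles(tr), nrow(tr$foot_mask),
                             ncol(tr$foot_mask))
    seg <- watershed_segment(tr$image, m, foot$foot_mask)
    expect_gte(iou(seg$ulcer_mask, tr$ulcer_mask), 0.90)
    expect_lt(abs(seg$n_ulcer_px - sum(tr$ulcer_mask)) / sum(tr$ulcer_mask),
              0.05)
  }
})

test_that("segmentation is robust to +/- 2 px scribble jitter", {
  tr <- generate_scene(scene_params())
  foot <- segment_foot(tr$image)
  scr <- truth_scribbles(tr)
  base <- watershed_segment(tr$image,
                            rasterize_scribbles(scr, 240L, 320L),
                            foot$foot_mask)$n_ulcer_px
  for (seed in 1:3) {
    jit <- jitter_scribbles(scr, 2L, seed)
    n <- watershed_segment(tr$image,
                           rasterize_scribbles(jit, 240L, 320L),
                           foot$foot_mask)$n_ulcer_px
    expect_lt(abs(n - base) / base, 0.05)
  }
})

test_that("boundary tracing follows the Moore-neighbor contract", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(extract_boundary(single), rbind(c(3, 3), c(3, 3)))
  block <- matrix(FALSE, 5, 5); block[2:3, 2:3] <- TRUE
  expect_equal(extract_boundary(block),
               rbind(c(2, 2), c(2, 3), c(3, 3), c(3, 2), c(2, 2)))
  expect_error(extract_boundary(matrix(FALSE, 3, 3)), class = "um_empty_mask")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(extract_boundary(two), class = "um_multiple_components")
  # contour pixels of a disc are exactly the mask's boundary pixels
  disc <- generate_scene(small_scene_params())$sticker_mask
  contour <- extract_boundary(disc)
  expect_equal(contour[1, ], contour[nrow(contour), ])
  expect_true(all(disc[contour]))
})

test_that("contour overlay paints pure green, copies, and is idempotent", {
  tr <- generate_scene(small_scene_params())
  seg <- watershed_segment(tr$image,
                           rasterize_scribbles(truth_scribbles(tr), 120L, 160L),
                           tr$foot_mask)
  before <- tr$image
  over <- overlay_contour(tr$image, seg$boundary_contour)
  expect_identical(tr$image, before)              # input untouched
  expect_identical(overlay_contour(over, seg$boundary_contour), over)
  pts <- unique(seg$boundary_contour)
  expect_true(all(over[cbind(pts, 2L)] == 255L))
  expect_true(all(over[cbind(pts, 1L)] == 0L))
  changed <- sum(over != tr$image)
  expect_lte(changed, 3L * nrow(seg$boundary_contour))
  expect_identical(overlay_contour(tr$image, matrix(integer(0), 0, 2)),
                   tr$image)
})
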