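fake_ulcer <- function(n_px, mask) {
  structure(list(ulcer_mask = mask, n_ulcer_px = n_px,
                 boundary_contour = matrix(integer(0), 0, 2)),
            class = "ulcer_segmentation")
}
fake_foot <- function(mask) {
  structure(list(foot_mask = mask, foot_area_px = sum(mask),
                 foot_centroid_px = mask_centroid_pub(mask)),
            class = "foot_segmentation")
}
mask_centroid_pub <- function(mask) {
  w <- which(mask, arr.ind = TRUE); c(mean(w[, 1]), mean(w[, 2]))
}
fake_scale <- function(ppc) structure(list(pixels_per_cm = ppc),
                                      class = "scale_estimate")

series_from_areas <- function(areas, days) {
  progress_series(data.frame(date = as.Date("2026-01-05") + days,
                             ulcer_area_cm2 = areas))
}

test_that("measurement combines areas, scale and ratio per definition", {
  foot_mask <- matrix(TRUE, 100, 100)
  ulcer_mask <- matrix(FALSE, 100, 100); ulcer_mask[1:20, 1:25] <- TRUE
  m <- measure(fake_ulcer(500L, ulcer_mask), fake_foot(foot_mask),
               fake_scale(40), "2026-01-05")
  expect_equal(m$area_ratio, 0.05)
  expect_equal(m$ulcer_area_cm2, 0.3125)
  m2 <- measure(fake_ulcer(1600L, ulcer_mask), fake_foot(foot_mask),
                fake_scale(40), "2026-01-05")
  expect_equal(m2$ulcer_area_cm2, 1.0)
  healed <- measure(fake_ulcer(0L, ulcer_mask & FALSE), fake_foot(foot_mask),
                    fake_scale(40), "2026-01-05")
  expect_equal(healed$area_ratio, 0)
  expect_equal(healed$ulcer_area_cm2, 0)
})

test_that("an ulcer outside the foot violates containment", {
  foot_mask <- matrix(FALSE, 10, 10); foot_mask[3:8, 3:8] <- TRUE
  stray <- matrix(FALSE, 10, 10); stray[1, 1] <- TRUE
  expect_error(measure(fake_ulcer(1L, stray), fake_foot(foot_mask),
                       fake_scale(10), "2026-01-05"),
               class = "um_containment_violation")
})

test_that("4-week assessment applies the strict >50% rule and the day window", {
  hx <- assess_healing(series_from_areas(c(4.0, 1.8), c(0, 28)))
  expect_equal(hx$percent_reduction, 55.0)
  expect_true(hx$on_track)
  exact <- assess_healing(series_from_areas(c(4.0, 2.0), c(0, 28)))
  expect_equal(exact$percent_reduction, 50.0)
  expect_false(exact$on_track)   # strict inequality
  expect_error(assess_healing(series_from_areas(c(4, 3), c(0, 14))),
               class = "um_no_assessment_point")
  # nearest measurement wins; the earlier one wins ties
  near <- assess_healing(series_from_areas(c(4, 3, 1), c(0, 27, 31)))
  expect_equal(near$assessment_area_cm2, 3)
  tie <- assess_healing(series_from_areas(c(4, 3, 1), c(0, 26, 30)))
  expect_equal(tie$assessment_area_cm2, 3)
  edge <- assess_healing(series_from_areas(c(4, 1), c(0, 25)))
  expect_equal(edge$assessment_area_cm2, 1)
})

test_that("percent-of-baseline curve starts at 100 and rejects a zero baseline", {
  curve <- percent_change_curve(series_from_areas(c(4, 3, 1.6), c(0, 7, 14)))
  expect_equal(curve$percent_of_baseline, c(100, 75, 40))
  single <- percent_change_curve(series_from_areas(2.5, 0))
  expect_equal(single$percent_of_baseline, 100)
  flat <- percent_change_curve(series_from_areas(c(2, 2, 2), c(0, 7, 14)))
  expect_equal(flat$percent_of_baseline, rep(100, 3))
  expect_error(percent_change_curve(series_from_areas(c(0, 1), c(0, 7))),
               class = "um_zero_baseline")
})

test_that("the percent curve is invariant to the scale estimate", {
  px <- c(6400, 4800, 2560)
  for (factor in c(0.8, 1.2)) {
    a <- series_from_areas(px / 40^2, c(0, 7, 14))
    b <- series_from_areas(px / (40 * factor)^2, c(0, 7, 14))
    expect_equal(percent_change_curve(a)$percent_of_baseline,
                 percent_change_curve(b)$percent_of_baseline)
  }
})

test_that("area ratio is invariant to uniform scene rescaling", {
  ratio_at <- function(k) {
    p <- scene_params(
      image_height_px = round(240 * k), image_width_px = round(320 * k),
      foot_semi_axes_px = c(100, 140) * k,
      foot_center_px = c(120.5, 160.5) * k,
      ulcer_vertices_px = default_ulcer_polygon(center = c(120, 100) * k,
                                                mean_radius = 20 * k),
      sticker_center_px = c(120.5, 230.5) * k,
      sticker_radius_px = 20 * k)
    tr <- generate_scene(p)
    sum(tr$ulcer_mask) / sum(tr$foot_mask)
  }
  expect_lt(abs(ratio_at(1.5) - ratio_at(1)) / ratio_at(1), 0.02)
})

test_that("reminders are due at the first anchor multiple strictly after now", {
  t0 <- as.POSIXct("2026-01-05 08:00:00", tz = "UTC")
  cfg <- reminder_config(interval = 2 * 24 * 60, anchor = t0)  # 2 days
  expect_equal(next_reminder(cfg, t0 + 3.5 * 86400), t0 + 4 * 86400)
  expect_equal(next_reminder(cfg, t0 - 100), t0 + 2 * 86400)
  expect_equal(next_reminder(cfg, t0 + 2 * 86400), t0 + 4 * 86400)  # strict >
  expect_equal(cfg$message, "Time to check your foot")
  expect_error(reminder_config(interval = 0, anchor = t0), class = "um_error")
})

test_that("the measurement log appends atomically and round-trips", {
  dir <- withr::local_tempdir()
  log <- file.path(dir, "log.csv")
  foot_mask <- matrix(TRUE, 50, 50)
  um <- matrix(FALSE, 50, 50); um[1:10, 1:10] <- TRUE
  m1 <- measure(fake_ulcer(100L, um), fake_foot(foot_mask), fake_scale(20),
                "2026-01-05")
  m2 <- measure(fake_ulcer(80L, um), fake_foot(foot_mask), fake_scale(20),
                "2026-01-12")
  append_measurement_log(m1, log)
  append_measurement_log(m2, log)
  s <- read_measurement_log(log)
  expect_equal(nrow(s), 2L)
  expect_equal(s$ulcer_area_cm2, c(100, 80) / 400)
  expect_false(file.exists(paste0(log, ".tmp")))
})
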