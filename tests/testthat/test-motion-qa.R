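# Build a geo_frame of the rendered phantom directly (no disk round trip).
phantom_frame <- function(displacement = c(0, 0), plane = "coronal",
                          noise_sd = 0, spacing_factor = 1,
                          body_offset = c(0, 0)) {
  n <- 256 * spacing_factor
  g <- acquisition_geometry(n, n, 256, 256)
  px <- render_phantom_frame(phantom_spec(), plane, displacement, g,
                             body_offset_mm = body_offset, noise_sd = noise_sd)
  assign_geometry(apply_centering_shift(px), plane,
                  c(g$pixel_spacing_row_mm, g$pixel_spacing_col_mm),
                  c(0, 0, 0), timestamp_ms = 0)
}

roi_rod <- function(spacing_factor = 1) {
  as.integer(round(c(96, 161, 74, 183) * spacing_factor))
}

make_trace <- function(time_s, du, dv = 0 * du, plane = "coronal") {
  structure(tibble::tibble(time_s = time_s, u_mm = du, v_mm = dv,
                           du_mm = du, dv_mm = dv),
            reference_mm = c(0, 0, 0), plane = plane,
            class = c("motion_trace", "tbl_df", "tbl", "data.frame"))
}

test_that("target segmentation recovers a rendered disc center to subpixel", {
  f <- phantom_frame(c(3.7, -2.1))
  seg <- segment_target(f, roi_rod())
  uv <- c(seg$centroid_mm[1], -seg$centroid_mm[3])  # coronal: u = x, v = -z
  expect_lt(sqrt(sum((uv - c(3.7, -2.1))^2)), 0.1)

  set.seed(99)
  fn <- phantom_frame(c(3.7, -2.1), noise_sd = 0.05)
  segn <- segment_target(fn, roi_rod())
  uvn <- c(segn$centroid_mm[1], -segn$centroid_mm[3])
  expect_lt(sqrt(sum((uvn - c(3.7, -2.1))^2)), 0.5)

  # uniform roi has no target
  expect_error(segment_target(f, c(1, 10, 1, 10)), "uniform")
  expect_error(segment_target(f, c(0, 10, 1, 10)), "roi")
})

test_that("centroid tracking follows programmed motion and records gaps", {
  frames <- lapply(0:9, function(k) {
    f <- phantom_frame(c(0, 0))
    f$timestamp_ms <- k * 200
    f
  })
  tr <- track_centroid(frames, roi_rod(), reference = c(0, 0, 0))
  expect_equal(nrow(tr), 10)
  expect_lt(max(abs(tr$du_mm)), 0.5)
  expect_lt(max(abs(tr$dv_mm)), 0.5)
  expect_equal(tr$time_s, seq(0, 1.8, by = 0.2))

  # one corrupted frame becomes a gap; trace length is preserved
  frames[[4]]$pixels <- matrix(100L, 256, 256)
  tr2 <- track_centroid(frames, roi_rod(), reference = c(0, 0, 0))
  expect_equal(nrow(tr2), 10)
  expect_true(is.na(tr2$du_mm[4]))
  expect_equal(sum(is.na(tr2$du_mm)), 1)

  # mixed planes are refused
  frames[[2]]$plane <- "axial"
  expect_error(track_centroid(frames, roi_rod(), reference = c(0, 0, 0)),
               "single plane")
})

test_that("a periodic fixture sequence yields a 4 s period within one frame", {
  frames <- lapply(0:79, function(k) {
    f <- phantom_frame(c(10 * sin(2 * pi * k * 0.2 / 4), 0))
    f$timestamp_ms <- k * 200
    f
  })
  tr <- track_centroid(frames, roi_rod(), reference = c(0, 0, 0))
  est <- estimate_amplitude(tr)
  expect_lt(abs(est$period_s - 4), 0.2)
  expect_lt(abs(est$mean_mm - 10), 0.3)
})

test_that("amplitude estimation matches a noise-free triangular ground truth", {
  t <- seq(0, 19.8, by = 0.2)
  tri <- 10 * (2 / pi) * asin(sin(2 * pi * t / 4))
  est <- estimate_amplitude(make_trace(t, tri))
  expect_lt(abs(est$mean_mm - 10), 0.5)
  expect_lte(est$sd_mm, 0.3)
  expect_gte(est$n_cycles, 2)

  # peak-to-peak mode doubles a symmetric waveform's amplitude
  est2 <- estimate_amplitude(make_trace(t, tri), mode = "peak_to_peak")
  expect_lt(abs(est2$mean_mm - 20), 1)

  # broom-style accessors
  expect_equal(nrow(tidy(est)), est$n_cycles)
  expect_equal(glance(est)$mean_mm, est$mean_mm)

  expect_error(estimate_amplitude(make_trace(t, rep(0, length(t)))),
               "insufficient cycles")
  one_cycle <- 5 * sin(2 * pi * seq(0, 3.8, by = 0.2) / 4)
  expect_error(estimate_amplitude(make_trace(seq(0, 3.8, by = 0.2), one_cycle)),
               "insufficient cycles")
})

test_that("translation registration is exact for identity and integer shifts", {
  f <- phantom_frame()
  reg0 <- register_translation(f, f)
  expect_equal(unname(reg0$shift_mm), c(0, 0))
  expect_gt(reg0$score, 0.9999)

  # integer roll of the pixel matrix: 3 px at 1 mm spacing
  g <- f
  rolled <- f$pixels
  rolled[, 4:ncol(rolled)] <- f$pixels[, 1:(ncol(rolled) - 3)]
  g$pixels <- rolled
  reg <- register_translation(f, g, roi = c(60, 200, 60, 200))
  expect_lt(abs(reg$shift_mm[["u"]] - 3), 0.05)
  expect_lt(abs(reg$shift_mm[["v"]]), 0.05)

  flat <- f; flat$pixels <- matrix(7L, 256, 256)
  expect_error(register_translation(f, flat), "no structure")
})

test_that("registration is antisymmetric and benefits from finer sampling", {
  a <- phantom_frame(body_offset = c(0, 0), plane = "sagittal")
  b <- phantom_frame(body_offset = c(1.7, 0), plane = "sagittal")
  roi <- c(156, 186, 100, 158)
  ab <- register_translation(a, b, roi = roi)
  ba <- register_translation(b, a, roi = roi)
  expect_lt(max(abs(ab$shift_mm + ba$shift_mm)), 0.05)
  expect_lt(abs(ab$shift_mm[["u"]] - 1.7), 0.1)

  # halving the pixel spacing must not increase the recovery error
  a2 <- phantom_frame(body_offset = c(0, 0), plane = "sagittal", spacing_factor = 2)
  b2 <- phantom_frame(body_offset = c(1.7, 0), plane = "sagittal", spacing_factor = 2)
  fine <- register_translation(a2, b2, roi = as.integer(round(c(156, 186, 100, 158) * 2)))
  err_coarse <- abs(ab$shift_mm[["u"]] - 1.7)
  err_fine <- abs(fine$shift_mm[["u"]] - 1.7)
  expect_lte(err_fine, err_coarse + 1e-3)
})

test_that("half-maximum profiles measure phantom dimensions to one pixel", {
  f <- phantom_frame(plane = "axial")  # axial: u = x, v = y
  rod <- measure_distance(f, c(-45, 0, 0), c(45, 0, 0))
  expect_lt(abs(rod - 58.5), 1)
  body <- measure_distance(f, c(-80, -40, 0), c(80, -40, 0))
  expect_lt(abs(body - 150.1), 1)
  # uniform profile has no edges
  expect_error(measure_distance(f, c(-20, -45, 0), c(20, -45, 0)), "no edges")
  expect_error(measure_distance(f, c(-500, 0, 0), c(500, 0, 0)), "outside")
})
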