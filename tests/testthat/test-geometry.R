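test_that("calibration divisor scales the raw Hough diameter", {
  ph <- clean_sphere_phase()
  f1 <- fit_sphere(ph, calibration_factor = 1.0)
  f2 <- fit_sphere(ph, calibration_factor = 1.08)
  expect_equal(f1$diameter_um, f1$diameter_raw_um)
  expect_equal(f2$diameter_raw_um, f1$diameter_raw_um)
  expect_equal(f2$diameter_um, f2$diameter_raw_um / 1.08)
  ## a raw 10.8 um circle calibrates to 10.0 um
  expect_equal(10.8 / f2$calibration_factor, 10, tolerance = 1e-12)
})

test_that("the calibrated diameter of a PSF-blurred sphere is accurate to 2%", {
  for (D in c(11.5, 13, 15)) {
    ph <- simulate_phase_object(
      synthetic_cell_spec(diameter_um = D, n_cell = 1.371), blurred_hcfg())
    ft <- fit_sphere(ph, calibration_factor = 1.08)
    expect_lt(abs(ft$diameter_um / D - 1), 0.02)
    ## centre lands on the true (sub-pixel) centre within a pixel
    expect_lt(max(abs(ft$center_px - c(127.5, 127.5))), 1)
  }
})

test_that("sphere fitting is translation-equivariant", {
  cfg <- blurred_hcfg()
  p1 <- simulate_phase_object(
    synthetic_cell_spec(diameter_um = 12, n_cell = 1.371,
                        center_px = c(110, 120)), cfg)
  p2 <- simulate_phase_object(
    synthetic_cell_spec(diameter_um = 12, n_cell = 1.371,
                        center_px = c(135, 145)), cfg)
  f1 <- fit_sphere(p1); f2 <- fit_sphere(p2)
  expect_equal(f2$center_px - f1$center_px, c(25, 25), tolerance = 0.6)
  expect_equal(f2$diameter_raw_um, f1$diameter_raw_um, tolerance = 0.01)
})

test_that("flat phase yields no circle", {
  expect_error(fit_sphere(phase_map(matrix(0, 128, 128), 0.1, 632.8)),
               "no circle")
})

test_that("projected thickness follows the chord-length formula", {
  ft <- manual_sphere_fit(12)
  tm <- thickness_map(ft, shape_px = c(256, 256))
  rr <- radius_grid_um()
  ## at the centre h = D (grid centre is 0.07 px off the true centre)
  expect_equal(max(tm$h), 12, tolerance = 1e-4)
  ## at r = (sqrt(3)/2) R the chord is R = D/2
  sel <- abs(rr - sqrt(3) / 2 * 6) < 0.005
  expect_equal(mean(tm$h[sel]), 6, tolerance = 0.05)
  ## zero outside the disc
  expect_true(all(tm$h[rr > 6.01] == 0))
})

test_that("integrated thickness converges to the sphere volume with resolution", {
  V <- 4 / 3 * pi * 6^3
  errs <- vapply(c(0.2, 0.1, 0.05), function(px) {
    n <- round(25.6 / px)
    ft <- manual_sphere_fit(12, center_px = (c(n, n) - 1) / 2, pixel_um = px)
    tm <- thickness_map(ft, shape_px = c(n, n))
    abs(sum(tm$h) * px^2 / V - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.005)          # 0.5% at pixel <= D/50
  expect_true(all(diff(errs) < 0))   # monotone improvement
})
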