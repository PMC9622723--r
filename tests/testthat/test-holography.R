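test_that("demodulating a pure carrier fringe returns near-zero phase", {
  ph0 <- simulate_phase_object(synthetic_cell_spec(n_cell = 1.335),
                               clean_hcfg())
  ig <- simulate_interferogram(ph0, clean_hcfg())
  fld <- demodulate(ig)
  w <- Arg(fld$values)
  inner <- w[9:248, 9:248]
  expect_lt(max(abs(inner)), 1e-3)
  expect_equal(fld$carrier, c(32, 32))
})

test_that("demodulation errors on a fringe-free image", {
  flat <- interferogram(matrix(1000, 128, 128), 0.1, 632.8)
  expect_error(demodulate(flat), "no carrier detected")
})

test_that("simulate-demodulate round trip recovers the phase", {
  ## study conditions: RMS < 1e-2 rad over the interior
  ig <- clean_sphere_interf()
  truth <- clean_sphere_phase()$phi
  rec <- remove_background(unwrap(demodulate(ig)), mask = truth > 0.1)
  err <- rec$phi - truth
  ## evaluated away from the image border and the cell rim, where the
  ## sharp-edged test object is not band-limited
  keep <- matrix(FALSE, 256, 256); keep[9:248, 9:248] <- TRUE
  keep <- keep & abs(radius_grid_um() - 6) >= 0.8
  expect_lt(sqrt(mean(err[keep]^2)), 1e-2)
  ## wrapped phase agrees with ground truth mod 2 pi
  w <- Arg(demodulate(ig)$values)
  werr <- (w - truth + pi) %% (2 * pi) - pi
  expect_lt(sqrt(mean(werr[keep]^2)), 1e-2)
})

test_that("round trip reaches 1e-3 RMS away from edges at fine sampling", {
  cell <- synthetic_cell_spec(diameter_um = 12, n_cell = 1.375)
  cfg <- hologram_sim_config(shape_px = c(512, 512), pixel_um = 0.05,
                             carrier_cycles = c(128, 128),
                             blur_sigma_px = 0, noise_sigma = 0)
  ph <- simulate_phase_object(cell, cfg)
  ig <- simulate_interferogram(ph, cfg)
  rec <- remove_background(unwrap(demodulate(ig, crop_frac = 0.248)),
                           mask = ph$phi > 0.1)
  err <- rec$phi - ph$phi
  rr <- radius_grid_um(512, 0.05)
  keep <- matrix(FALSE, 512, 512); keep[17:496, 17:496] <- TRUE
  keep <- keep & abs(rr - 6) >= 1   # away from the cell rim
  expect_lt(sqrt(mean(err[keep]^2)), 1e-3)
})

test_that("unwrap satisfies the exact mod-2pi congruence contract", {
  ## plane spanning 10 rad: recovered exactly up to a global 2 pi k
  plane <- outer(seq(0, 10, length.out = 64), seq(0, 0, length.out = 64), "+")
  wrapped <- (plane + pi) %% (2 * pi) - pi
  uw <- unwrap(wrapped, pixel_um = 0.1, lambda_q_nm = 632.8)
  offs <- (uw$phi - plane)[1, 1]
  expect_equal(offs %% (2 * pi), 0, tolerance = 1e-9)
  expect_equal(uw$phi - plane, matrix(offs, 64, 64), tolerance = 1e-9)
  ## all-zero input stays zero
  z <- unwrap(matrix(0, 32, 32), pixel_um = 0.1, lambda_q_nm = 632.8)
  expect_true(all(z$phi == 0))
  ## spherical cap with peak 4.77 rad: exact recovery after wrap
  truth <- clean_sphere_phase()$phi
  wrapped <- (truth + pi) %% (2 * pi) - pi
  uw2 <- unwrap(wrapped, pixel_um = 0.1, lambda_q_nm = 632.8)
  expect_lt(max(abs(uw2$phi - truth)), 1e-3)
  ## congruence holds pixelwise on rough random fields too
  set.seed(11)
  for (k in 1:3) {
    surf <- 3 * outer(sin(seq(0, 2, length.out = 48)),
                      cos(seq(0, 3, length.out = 48))) +
      matrix(rnorm(48^2, 0, 0.3), 48, 48)
    wr <- (surf + pi) %% (2 * pi) - pi
    uu <- unwrap(wr, pixel_um = 0.1, lambda_q_nm = 632.8)
    d <- (uu$phi - wr) / (2 * pi)
    expect_equal(d, round(d), tolerance = 1e-9)
  }
})

test_that("background removal cancels a pure polynomial surface", {
  terms <- outer(seq(-1, 1, length.out = 128)^2, rep(1, 128)) +
    0.5 * outer(seq(-1, 1, length.out = 128), seq(-1, 1, length.out = 128))
  pm <- phase_map(terms, 0.1, 632.8)
  fake_mask <- matrix(FALSE, 128, 128); fake_mask[40:60, 40:60] <- TRUE
  out <- remove_background(pm, mask = fake_mask, poly_order = 2)
  expect_lt(max(abs(out$phi)), 1e-6)
  ## order 0 subtracts the mean only
  out0 <- remove_background(pm, mask = NULL, poly_order = 0)
  expect_equal(out0$phi, terms - mean(terms), tolerance = 1e-9)
  ## idempotency
  twice <- remove_background(out, mask = fake_mask, poly_order = 2)
  expect_lt(sqrt(mean((twice$phi - out$phi)^2)), 1e-6)
  ## too few background pixels
  allcell <- matrix(TRUE, 128, 128); allcell[1, 1:20] <- FALSE
  expect_error(remove_background(pm, mask = allcell),
               "insufficient background")
})

test_that("a simulated polynomial background is removed from the cell phase", {
  bgc <- matrix(0, 3, 3); bgc[1, 2] <- 0.3; bgc[2, 1] <- -0.2; bgc[3, 1] <- 0.25
  cfg <- hologram_sim_config(background_coeffs = bgc, blur_sigma_px = 0,
                             noise_sigma = 0)
  cell <- synthetic_cell_spec(diameter_um = 12, n_cell = 1.375)
  ph <- simulate_phase_object(cell, cfg)
  ig <- simulate_interferogram(ph, cfg)
  rec <- process_hologram(ig, pipeline_config())
  err <- rec$phi - ph$phi
  keep <- matrix(FALSE, 256, 256); keep[9:248, 9:248] <- TRUE
  keep <- keep & abs(radius_grid_um() - 6) >= 0.8
  expect_lt(sqrt(mean(err[keep]^2)), 1e-2)
})

test_that("segmentation recovers the disc and picks the dominant object", {
  ph <- clean_sphere_phase()
  m <- segment_cell(ph)
  truth <- ph$ground_truth$thickness_um > 0
  iou <- sum(m & truth) / sum(m | truth)
  expect_gte(iou, 0.95)
  expect_identical(attr(m, "n_components"), 1L)
  ## flat phase: nothing to segment
  expect_error(segment_cell(phase_map(matrix(0, 64, 64), 0.1, 632.8)),
               "no cell found")
  ## two discs: the one with larger integrated phase wins, both reported
  h1 <- sphere_thickness_grid(c(256, 256), c(70, 70), 10, 0.1)
  h2 <- sphere_thickness_grid(c(256, 256), c(180, 180), 13, 0.1)
  two <- phase_map(0.3 * h1 + 0.4 * h2, 0.1, 632.8)
  m2 <- segment_cell(two)
  expect_identical(attr(m2, "n_components"), 2L)
  expect_true(m2[180, 180])
  expect_false(m2[70, 70])
})
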