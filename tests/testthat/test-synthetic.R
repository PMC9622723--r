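test_that("simulated sphere phase matches the analytic forward model", {
  ph <- clean_sphere_phase()
  ## centre phase = 2 pi dn D / lambda
  expect_equal(max(ph$phi), 2 * pi * 0.040 * 12 / 0.6328, tolerance = 1e-3)
  ## blur-free phase equals the analytic thickness formula at every pixel
  h <- ph$ground_truth$thickness_um
  expect_equal(ph$phi, 2 * pi / 0.6328 * 0.040 * h, tolerance = 1e-12)
  ## zero contrast cell gives identically zero phase
  ph0 <- simulate_phase_object(synthetic_cell_spec(n_cell = 1.335),
                               clean_hcfg())
  expect_true(all(ph0$phi == 0))
})

test_that("a sphere that does not fit in the field is rejected", {
  expect_error(
    simulate_phase_object(synthetic_cell_spec(diameter_um = 30), clean_hcfg()),
    "out of field")
  expect_error(
    simulate_phase_object(
      synthetic_cell_spec(diameter_um = 12, center_px = c(30, 127)),
      clean_hcfg()),
    "out of field")
})

test_that("interferogram simulation is seeded-deterministic and guards saturation", {
  cfg <- hologram_sim_config(noise_sigma = 0.01, seed = 7)
  ph <- clean_sphere_phase()
  i1 <- simulate_interferogram(ph, cfg)
  i2 <- simulate_interferogram(ph, cfg)
  expect_identical(i1$pixels, i2$pixels)
  expect_true(all(i1$pixels == round(i1$pixels)))
  ## gross noise drives pixels to the maximum code -> saturation error
  expect_error(
    simulate_interferogram(ph, hologram_sim_config(noise_sigma = 3, seed = 1)),
    "saturation")
  ## too low a carrier cannot separate the sideband from DC
  expect_error(
    simulate_interferogram(ph, hologram_sim_config(carrier_cycles = c(3, 3),
                                                   noise_sigma = 0)),
    "carrier too low")
})

test_that("phase-flat interferogram is a pure carrier fringe", {
  ph0 <- simulate_phase_object(synthetic_cell_spec(n_cell = 1.335),
                               clean_hcfg())
  ig <- simulate_interferogram(ph0, clean_hcfg())
  ## intensity must be exactly periodic with the carrier (8 px at 32 cycles
  ## over 256 px)
  expect_equal(ig$pixels[1:248, ], ig$pixels[9:256, ], tolerance = 0)
})

test_that("simulated Brillouin peak width is intrinsic plus instrument FWHM", {
  cs <- synthetic_cell_spec(nu_b_ghz = 7.865, gamma_true_ghz = 1.279)
  sp <- simulate_brillouin_spectrum(cs, clean_scfg())
  expect_equal(sp$ground_truth$measured_fwhm_ghz, 1.677)
  ## the fitted FWHM of the noise-free simulated peak confirms it
  res <- analyze_spectrum(sp)
  expect_equal(res$gamma_measured_ghz, 1.677, tolerance = 2e-3)
})

test_that("spectrum simulation is seeded and supports degenerate amplitudes", {
  cs <- synthetic_cell_spec()
  s1 <- simulate_brillouin_spectrum(cs, spectrum_sim_config(seed = 3))
  s2 <- simulate_brillouin_spectrum(cs, spectrum_sim_config(seed = 3))
  expect_identical(s1$counts, s2$counts)
  ## no Brillouin amplitude -> only the elastic line remains
  s0 <- simulate_brillouin_spectrum(cs, clean_scfg(brillouin_amplitude = 0))
  f <- ghz_axis(s0)
  expect_true(all(s0$counts[abs(f) > 2] < 0.01 * max(s0$counts)))
  ## overlapping peaks carry a warning flag
  swide <- simulate_brillouin_spectrum(
    synthetic_cell_spec(nu_b_ghz = 2, gamma_true_ghz = 1.6), clean_scfg())
  expect_true(isTRUE(attr(swide, "overlap_warning")))
})

test_that("cohort draws are seeded, truncated and converge to the population mean", {
  expect_equal(nrow(draw_cohort_params(cohort_spec(n_cells = 0))), 0)
  c1 <- draw_cohort_params(cohort_preset("control", seed = 9))
  c2 <- draw_cohort_params(cohort_preset("control", seed = 9))
  expect_identical(c1, c2)
  ## law of large numbers at n = 1e4: mean within 3 SE of the spec mean
  big <- draw_cohort_params(cohort_spec(n_cells = 1e4, seed = 2))
  se <- 1.8 / sqrt(1e4)
  expect_lt(abs(mean(big$diameter_um) - 12.9), 3 * se)
  ## physical truncation
  expect_true(all(big$n_cell >= 1.335))
  expect_true(all(big$gamma_b_ghz > 0))
})

test_that("rendered cohorts are reproducible and carry ground truth", {
  spec <- cohort_spec(n_cells = 2, seed = 5)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_length(a, 2)
  expect_identical(a[[1]]$interferogram$pixels, b[[1]]$interferogram$pixels)
  expect_identical(a[[2]]$spectrum$counts, b[[2]]$spectrum$counts)
  expect_equal(a[[1]]$truth$diameter_um,
               a[[1]]$interferogram$ground_truth$spec$diameter_um)
})
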