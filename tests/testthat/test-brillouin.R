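test_that("pixel-to-GHz calibration is anchored to the free spectral range", {
  co <- pixel_to_ghz(c(100, 900), fsr_ghz = 29.95)
  at <- function(px) sum(co * px^(seq_along(co) - 1))
  expect_equal(at(500), 14.975, tolerance = 1e-9)
  expect_equal(at(100), 0, tolerance = 1e-9)
  expect_equal(at(900), 29.95, tolerance = 1e-9)
  expect_error(pixel_to_ghz(c(100, 100)), "distinct")
  expect_error(pixel_to_ghz(150), "at least two")
  ## quadratic dispersion recovered within 0.5% from three anchors
  true_co <- c(-15, 0.055, 6e-6)
  f_of <- function(px) true_co[1] + true_co[2] * px + true_co[3] * px^2
  anchors <- vapply(c(-14.975, 0, 14.975), function(g)
    stats::uniroot(function(p) f_of(p) - g, c(0, 600))$root,
    numeric(1))
  co2 <- pixel_to_ghz(anchors, fsr_ghz = 14.975, origin = 2L)
  px <- seq(min(anchors), max(anchors), length.out = 50)
  est <- co2[1] + co2[2] * px + co2[3] * px^2
  expect_lt(max(abs(est - (f_of(px) - f_of(anchors[2])))), 0.005 * 29.95)
})

test_that("noise-free Lorentzian pair is fitted to MHz accuracy", {
  cs <- synthetic_cell_spec(nu_b_ghz = 7.865, gamma_true_ghz = 1.279)
  pk <- locate_and_fit_peaks(simulate_brillouin_spectrum(cs, clean_scfg()))
  expect_lt(abs(pk$stokes$center_ghz - (-7.865)), 1e-3)
  expect_lt(abs(pk$antistokes$center_ghz - 7.865), 1e-3)
  expect_lt(abs(pk$stokes$fwhm_ghz - 1.677), 2e-3)
  expect_lt(abs(pk$antistokes$fwhm_ghz - 1.677), 2e-3)
})

test_that("degenerate spectra raise peak-not-found errors", {
  flat <- brillouin_spectrum(rep(100, 512), c(-14.975, 29.95 / 511), 29.95)
  expect_error(locate_and_fit_peaks(flat), "peak not found")
  only_el <- simulate_brillouin_spectrum(
    synthetic_cell_spec(), clean_scfg(brillouin_amplitude = 0))
  expect_error(locate_and_fit_peaks(only_el), "peak not found")
})

test_that("half-distance shift rule and its invariances", {
  mk <- function(c) structure(list(center_ghz = c, fwhm_ghz = 1,
                                   amplitude = 1, offset = 0,
                                   resid_norm = 0),
                              class = "lorentzian_peak")
  expect_equal(brillouin_shift(mk(-7.9), mk(7.9)), 7.9)
  expect_equal(brillouin_shift(mk(-7.80), mk(7.93)), 7.865)
  expect_warning(out <- brillouin_shift(mk(1), mk(1)), "coincident")
  expect_equal(out, 0)
  ## invariant under a global frequency offset
  expect_equal(brillouin_shift(mk(-7.8 + 0.3), mk(7.93 + 0.3)), 7.865)
})

test_that("linewidth correction is a guarded linear subtraction", {
  expect_equal(correct_linewidth(1.677, 0.398), 1.279)
  expect_equal(correct_linewidth(1.5, 0), 1.5)
  expect_error(correct_linewidth(0.398, 0.398), "below instrument")
})

test_that("SNR follows the amplitude-over-residual-SD definition", {
  ## synthetic spectrum with known flat Gaussian noise
  cs <- synthetic_cell_spec()
  cfg <- spectrum_sim_config(noise_model = "gaussian",
                             brillouin_amplitude = 1585 * 40,
                             elastic_amplitude = 2 * 1585 * 40,
                             noise_sigma = 40, seed = 8)
  sp <- simulate_brillouin_spectrum(cs, cfg)
  pk <- locate_and_fit_peaks(sp)
  expect_equal(spectrum_snr(sp, pk), 10 * log10(1585), tolerance = 0.5)
  ## noise-free spectra hit the documented cap
  sp0 <- simulate_brillouin_spectrum(cs, clean_scfg())
  expect_equal(spectrum_snr(sp0, locate_and_fit_peaks(sp0)), 99)
})

test_that("shift repeatability at ~32 dB is within 10 MHz", {
  cs <- synthetic_cell_spec(nu_b_ghz = 7.865, gamma_true_ghz = 1.279)
  shifts <- vapply(1:30, function(i) {
    sp <- simulate_brillouin_spectrum(cs, spectrum_sim_config(seed = 300 + i))
    analyze_spectrum(sp)$nu_b_ghz
  }, numeric(1))
  expect_lte(stats::sd(shifts) * 1e3, 10)
})

test_that("fits stay accurate across the physiological shift and SNR range", {
  nu_err <- c(); gam_err <- c()
  for (nu in c(7.0, 7.8, 8.5)) for (amp in c(3e4, 3e5)) {
    for (s in 1:4) {
      cs <- synthetic_cell_spec(nu_b_ghz = nu, gamma_true_ghz = 1.279)
      cfg <- spectrum_sim_config(brillouin_amplitude = amp,
                                 elastic_amplitude = 2 * amp,
                                 seed = 7000 + s)
      res <- analyze_spectrum(simulate_brillouin_spectrum(cs, cfg))
      nu_err <- c(nu_err, abs(res$nu_b_ghz - nu))
      gam_err <- c(gam_err, abs(res$gamma_b_ghz - 1.279))
    }
  }
  expect_lte(stats::median(nu_err) * 1e3, 10)
  expect_lte(stats::median(gam_err) * 1e3, 30)
})

test_that("percent change matches the NA-calibration arithmetic", {
  expect_equal(relative_change(8.407, 8.172), -2.8, tolerance = 0.05)
  expect_equal(relative_change(1.048, 1.045), -0.3, tolerance = 0.05)
  expect_equal(relative_change(5, 5), 0)
  expect_error(relative_change(0, 1), "zero")
})
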