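test_that("RI map inverts the forward phase model", {
  ph <- clean_sphere_phase()             # D = 12, dn = 0.040
  ft <- manual_sphere_fit(12)
  tm <- thickness_map(ft, shape_px = c(256, 256))
  dn <- ri_map(ph, tm)
  rr <- radius_grid_um()
  inside <- rr < 5.4
  expect_equal(mean(dn[inside]), 0.040, tolerance = 1e-3)
  expect_lt(stats::sd(dn[inside]), 1e-3)  # uniform interior
  expect_true(all(is.na(dn[tm$h == 0])))
  ## zero phase -> zero contrast
  dn0 <- ri_map(phase_map(matrix(0, 256, 256), 0.1, 632.8), tm)
  expect_true(all(dn0[inside] == 0))
})

test_that("mean RI averages the interior and adds the medium index", {
  ft <- manual_sphere_fit(12)
  dn <- matrix(0.036, 256, 256)
  expect_equal(mean_ri(dn, ft), 1.371, tolerance = 1e-12)
  ## degenerate: cell smaller than a pixel leaves no interior
  tiny <- manual_sphere_fit(0.05)
  expect_error(mean_ri(dn, tiny), "no valid interior")
})

test_that("dry mass matches the closed form for a uniform sphere", {
  ## m_dry = dn * V / alpha = 0.036 * 1150.35 / 0.2 = 207.1 pg
  ph <- simulate_phase_object(
    synthetic_cell_spec(diameter_um = 13, n_cell = 1.371), clean_hcfg())
  m <- dry_mass(ph)   # whole-frame integral of a background-free image
  expect_equal(m, 0.036 * (4 / 3) * pi * 6.5^3 / 0.2, tolerance = 0.002)
  ## doubling alpha halves the mass
  m2 <- dry_mass(ph, consts = physical_constants(alpha_ml_per_g = 0.4))
  expect_equal(m2, m / 2, tolerance = 1e-12)
  ## zero phase -> zero mass; negative phase warns but returns
  z <- phase_map(matrix(0, 64, 64), 0.1, 632.8)
  expect_equal(dry_mass(z), 0)
  neg <- phase_map(matrix(-0.01, 64, 64), 0.1, 632.8)
  expect_warning(mneg <- dry_mass(neg), "negative")
  expect_lt(mneg, 0)
})

test_that("mixture model reproduces the two-compartment arithmetic", {
  ## control-like cell: V_cell = 1175 um^3 -> D, dry mass 225 pg
  D <- 2 * (3 * 1175 / (4 * pi))^(1 / 3)
  mix <- mixture_model(D, 225)
  expect_equal(mix$v_cell_um3, 1175, tolerance = 1e-9)
  expect_equal(mix$v_dry_um3, 164.2, tolerance = 0.05)
  expect_equal(mix$v_fluid_um3, 1010.8, tolerance = 0.05)
  expect_equal(mix$rho_g_per_ml, (225 + 1010.766) / 1175, tolerance = 1e-4)
  ## pure-water limit
  mix0 <- mixture_model(13, 0)
  expect_equal(mix0$rho_g_per_ml, 1)
  expect_equal(mix0$u_h2o_pct, 100)
  expect_equal(mix0$theta_h2o_pct, 100)
  ## impossible dry volume
  expect_error(mixture_model(5, 1e4), "dry volume exceeds")
})

test_that("mixture model conserves mass and volume and respects bounds", {
  set.seed(4)
  for (k in 1:25) {
    D <- runif(1, 8, 18)
    v_cell <- 4 / 3 * pi * (D / 2)^3
    m <- runif(1, 0, 1.37 * v_cell)
    mix <- mixture_model(D, m)
    expect_equal(mix$v_dry_um3 + mix$v_fluid_um3, mix$v_cell_um3)
    expect_equal(mix$rho_g_per_ml * mix$v_cell_um3, m + mix$m_fluid_pg)
    expect_gte(mix$rho_g_per_ml, 1); expect_lte(mix$rho_g_per_ml, 1.37)
    ## water volume fraction exceeds the mass fraction (rho_dry > rho_fluid)
    expect_gte(mix$theta_h2o_pct, mix$u_h2o_pct)
    expect_true(mix$u_h2o_pct >= 0 && mix$theta_h2o_pct <= 100)
  }
})
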