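## Forward simulators: spherical phase objects on a tilted-fringe carrier,
## and VIPA Brillouin spectra with an elastic line plus a Stokes/anti-Stokes
## Lorentzian pair. These define the study conditions under which every
## analysis stage is tested.

#' Ground-truth description of one synthetic spherical cell
#'
#' @param diameter_um Cell diameter (um), > 0.
#' @param n_cell Cell mean refractive index; must be >= \code{n_medium}.
#' @param center_px Sub-pixel (row, col) centre of the cell in the field.
#' @param n_medium Medium refractive index.
#' @param nu_b_ghz Brillouin shift (GHz); must be below half the free
#'   spectral range so both peaks stay within one order.
#' @param gamma_true_ghz Intrinsic Brillouin linewidth FWHM (GHz), > 0.
#' @return Object of class \code{synthetic_cell_spec}.
#' @export
synthetic_cell_spec <- function(diameter_um = 12.9, n_cell = 1.371,
                                center_px = NULL, n_medium = 1.335,
                                nu_b_ghz = 7.865, gamma_true_ghz = 1.279) {
  if (diameter_um <= 0) stop("diameter_um must be > 0")
  if (n_cell < n_medium) stop("n_cell must be >= n_medium")
  if (gamma_true_ghz <= 0) stop("gamma_true_ghz must be > 0")
  structure(list(diameter_um = diameter_um, n_cell = n_cell,
                 center_px = center_px, n_medium = n_medium,
                 nu_b_ghz = nu_b_ghz, gamma_true_ghz = gamma_true_ghz),
            class = "synthetic_cell_spec")
}

#' Configuration of the hologram forward model
#'
#' The carrier is expressed in cycles across the field per axis (the paper's
#' beam angle depends on optics not modelled here); the default puts the
#' sideband at about one quarter of Nyquist, comfortably separating it from
#' the DC term. Optical blur is modelled as a Gaussian point-spread function
#' applied to the phase map; the default sigma is matched so that the raw
#' circular Hough diameter overestimates truth by ~8\%, the bias the 1.08
#' calibration divisor compensates.
#'
#' @param shape_px Integer (rows, cols) of the simulated camera frame.
#' @param pixel_um Pixel pitch (um/px).
#' @param lambda_q_nm Illumination wavelength (nm).
#' @param carrier_cycles Fringe frequency per axis (cycles across the field).
#' @param background_coeffs Matrix of 2-D polynomial coefficients (radians);
#'   entry [i, j] multiplies x^(i-1) * y^(j-1) on [-1, 1]-normalized coords.
#' @param blur_sigma_px Gaussian PSF sigma (px) applied to the phase map.
#' @param noise_sigma Additive Gaussian intensity noise, as a fraction of the
#'   fringe amplitude.
#' @param seed RNG seed for the noise.
#' @return Object of class \code{hologram_sim_config}.
#' @export
hologram_sim_config <- function(shape_px = c(256L, 256L), pixel_um = 0.1,
                                lambda_q_nm = 632.8,
                                carrier_cycles = c(32, 32),
                                background_coeffs = matrix(0, 1, 1),
                                blur_sigma_px = 6, noise_sigma = 0.01,
                                seed = 1L) {
  stopifnot(length(shape_px) == 2, all(shape_px >= 32),
            pixel_um > 0, length(carrier_cycles) == 2,
            is.matrix(background_coeffs), blur_sigma_px >= 0,
            noise_sigma >= 0)
  structure(list(shape_px = as.integer(shape_px), pixel_um = pixel_um,
                 lambda_q_nm = lambda_q_nm, carrier_cycles = carrier_cycles,
                 background_coeffs = background_coeffs,
                 blur_sigma_px = blur_sigma_px, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "hologram_sim_config")
}

#' Configuration of the Brillouin spectrum forward model
#'
#' Instrument broadening is applied as a linear FWHM addition (simulated
#' peak FWHM = intrinsic + instrument), the exact counterpart of the linear
#' subtraction used by \code{\link{correct_linewidth}}. Default amplitudes
#' give a fitted peak signal-to-noise ratio of about 32 dB under Poisson
#' noise, the level reported for cell spectra.
#'
#' @param n_px Number of detector pixels.
#' @param dispersion_coeffs Pixel-to-GHz polynomial (c0, c1, ...); default is
#'   linear spanning one free spectral range centred on the elastic line.
#' @param fsr_ghz Free spectral range (GHz).
#' @param instrument_fwhm_ghz Instrument response FWHM (GHz).
#' @param elastic_amplitude Elastic (unshifted) line peak height (counts).
#' @param brillouin_amplitude Brillouin peak height (counts).
#' @param baseline Constant background level (counts).
#' @param noise_model "poisson", "gaussian" or "none".
#' @param noise_sigma Gaussian noise SD (counts), used when
#'   \code{noise_model = "gaussian"}.
#' @param seed RNG seed.
#' @return Object of class \code{spectrum_sim_config}.
#' @export
spectrum_sim_config <- function(n_px = 512L,
                                dispersion_coeffs = NULL,
                                fsr_ghz = 29.95,
                                instrument_fwhm_ghz = 0.398,
                                elastic_amplitude = 2e5,
                                brillouin_amplitude = 1e5,
                                baseline = 20,
                                noise_model = c("poisson", "gaussian", "none"),
                                noise_sigma = 0,
                                seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_px >= 64, fsr_ghz > 0, instrument_fwhm_ghz >= 0,
            elastic_amplitude >= 0, brillouin_amplitude >= 0, baseline >= 0)
  if (is.null(dispersion_coeffs))
    dispersion_coeffs <- c(-fsr_ghz / 2, fsr_ghz / (n_px - 1))
  f <- eval_poly(dispersion_coeffs, seq_len(n_px) - 1)
  if (any(diff(f) <= 0)) stop("dispersion must be strictly increasing")
  structure(list(n_px = as.integer(n_px),
                 dispersion_coeffs = dispersion_coeffs, fsr_ghz = fsr_ghz,
                 instrument_fwhm_ghz = instrument_fwhm_ghz,
                 elastic_amplitude = elastic_amplitude,
                 brillouin_amplitude = brillouin_amplitude,
                 baseline = baseline, noise_model = noise_model,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "spectrum_sim_config")
}

## Analytic projected thickness of a sphere on the pixel grid (um).
sphere_thickness_grid <- function(shape_px, center_px, diameter_um, pixel_um) {
  rows <- seq_len(shape_px[1]) - 1
  cols <- seq_len(shape_px[2]) - 1
  R <- diameter_um / 2
  dr2 <- outer(((rows - center_px[1]) * pixel_um)^2,
               ((cols - center_px[2]) * pixel_um)^2, "+")
  h <- 2 * sqrt(pmax(R^2 - dr2, 0))
  h
}

#' Simulate the phase map of a spherical phase object
#'
#' Builds phi(x, y) = (2 pi / lambda_Q) (n_cell - n_medium) h(x, y) where
#' h is the projected sphere thickness 2 sqrt((D/2)^2 - r^2) inside the disc
#' and 0 outside, then optionally applies a Gaussian blur emulating the
#' objective's point-spread function. The returned phase map carries the
#' ground-truth spec in \code{$ground_truth}.
#'
#' @param spec A \code{\link{synthetic_cell_spec}}.
#' @param cfg A \code{\link{hologram_sim_config}}.
#' @return A \code{\link{phase_map}} (no mask).
#' @examples
#' ph <- simulate_phase_object(synthetic_cell_spec(diameter_um = 12),
#'                             hologram_sim_config())
#' max(ph$phi)
#' @export
simulate_phase_object <- function(spec, cfg) {
  stopifnot(inherits(spec, "synthetic_cell_spec"),
            inherits(cfg, "hologram_sim_config"))
  center <- spec$center_px
  if (is.null(center)) center <- (cfg$shape_px - 1) / 2
  R_px <- spec$diameter_um / 2 / cfg$pixel_um
  margin <- 1.1 * R_px
  if (center[1] - margin < 0 || center[2] - margin < 0 ||
      center[1] + margin > cfg$shape_px[1] - 1 ||
      center[2] + margin > cfg$shape_px[2] - 1)
    stop("object out of field")
  h <- sphere_thickness_grid(cfg$shape_px, center, spec$diameter_um,
                             cfg$pixel_um)
  lambda_um <- cfg$lambda_q_nm * .NM_TO_UM
  phi <- 2 * pi / lambda_um * (spec$n_cell - spec$n_medium) * h
  if (cfg$blur_sigma_px > 0)
    phi <- gaussian_blur(phi, cfg$blur_sigma_px)
  gt <- list(spec = spec, center_px = center, thickness_um = h)
  phase_map(phi, cfg$pixel_um, cfg$lambda_q_nm, ground_truth = gt)
}

## Gaussian blur of a matrix via EBImage (boundary replication keeps the
## total phase integral nearly conserved for interior objects).
gaussian_blur <- function(m, sigma_px) {
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma_px,
                           boundary = "replicate"))
}

#' Simulate an off-axis interferogram from a phase map
#'
#' Records I = |A_r exp(i k.x) + A_s exp(i (phi + bg))|^2, i.e. a tilted
#' fringe carrier modulated by the object phase plus a smooth polynomial
#' background phase, with optional additive Gaussian intensity noise, and
#' quantizes to the 16-bit camera range. Errors if any pixel saturates or if
#' the carrier is too low for the object sideband to separate from DC.
#'
#' @param phase A \code{\link{phase_map}} (typically from
#'   \code{\link{simulate_phase_object}}).
#' @param cfg A \code{\link{hologram_sim_config}}.
#' @return An \code{\link{interferogram}} with integer-valued counts;
#'   simulation ground truth is carried through.
#' @export
simulate_interferogram <- function(phase, cfg) {
  stopifnot(inherits(phase, "phase_map"), inherits(cfg, "hologram_sim_config"))
  nr <- nrow(phase$phi); nc <- ncol(phase$phi)
  rows <- seq_len(nr) - 1; cols <- seq_len(nc) - 1
  carrier <- 2 * pi * (outer(cfg$carrier_cycles[1] * rows / nr, rep(0, nc), "+") +
                       outer(rep(0, nr), cfg$carrier_cycles[2] * cols / nc, "+"))
  bg <- poly2d_eval(cfg$background_coeffs, nr, nc)
  phi <- phase$phi + bg
  check_sideband_separation(phi, cfg$carrier_cycles)
  ## unit-amplitude beams; fringe term amplitude 2*Ar*As
  Ar <- 0.5; As <- 0.5
  I <- Ar^2 + As^2 + 2 * Ar * As * cos(carrier - phi)
  fringe_amp <- 2 * Ar * As
  if (cfg$noise_sigma > 0) {
    I <- I + withr::with_seed(cfg$seed,
      matrix(stats::rnorm(nr * nc, 0, cfg$noise_sigma * fringe_amp), nr, nc))
  }
  ## map [0, 1] intensity to 16-bit codes with headroom; clamp negatives
  codes <- round(pmax(I, 0) / 1.0 * 58000)
  if (any(codes >= 65535)) stop("detector saturation: pixel at max code")
  interferogram(codes, phase$pixel_um, phase$lambda_q_nm,
                ground_truth = c(phase$ground_truth,
                                 list(phase = phase$phi, background = bg)))
}

## 2-D polynomial on [-1,1] x [-1,1] normalized coordinates.
## coeffs[i, j] multiplies u^(i-1) * v^(j-1), u along rows, v along cols.
poly2d_eval <- function(coeffs, nr, nc) {
  u <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  v <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(coeffs))) for (j in seq_len(ncol(coeffs))) {
    if (coeffs[i, j] != 0)
      out <- out + coeffs[i, j] * outer(u^(i - 1), v^(j - 1))
  }
  out
}

## Sideband separation check: the object's spectral radius (97% energy of
## exp(i*phi)) must stay below 1/3 of the carrier offset.
check_sideband_separation <- function(phi, carrier_cycles) {
  nr <- nrow(phi); nc <- ncol(phi)
  F <- stats::fft(exp(1i * phi))
  P <- Mod(F)^2
  fr <- ifelse(0:(nr - 1) > nr / 2, 0:(nr - 1) - nr, 0:(nr - 1))
  fc <- ifelse(0:(nc - 1) > nc / 2, 0:(nc - 1) - nc, 0:(nc - 1))
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  ord <- order(rad)
  cum <- cumsum(P[ord]) / sum(P)
  r97 <- rad[ord][which(cum >= 0.97)[1]]
  if (sqrt(sum(carrier_cycles^2)) < 3 * r97)
    stop("carrier too low: sideband would not separate from DC (need >= 3x object bandwidth)")
  invisible(r97)
}

## Lorentzian line with unit peak amplitude.
lorentz <- function(f, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((f - center)^2 + hw2)
}

#' Simulate a VIPA Brillouin spectrum
#'
#' Counts(px) = elastic line at 0 GHz (FWHM = instrument response) plus a
#' Stokes/anti-Stokes Lorentzian pair at -/+ nu_B whose FWHM is the intrinsic
#' linewidth plus the instrument FWHM (linear broadening, the counterpart of
#' the linear linewidth correction), plus a constant baseline and seeded
#' noise. If the Brillouin peaks are not resolvable from the elastic line a
#' warning flag is attached (attribute \code{overlap_warning}).
#'
#' @param spec A \code{\link{synthetic_cell_spec}} (uses \code{nu_b_ghz},
#'   \code{gamma_true_ghz}).
#' @param cfg A \code{\link{spectrum_sim_config}}.
#' @return A \code{\link{brillouin_spectrum}} with ground truth attached.
#' @export
simulate_brillouin_spectrum <- function(spec, cfg) {
  stopifnot(inherits(spec, "synthetic_cell_spec"),
            inherits(cfg, "spectrum_sim_config"))
  if (spec$nu_b_ghz >= cfg$fsr_ghz / 2)
    stop("nu_b_ghz must be below FSR/2 (single-order convention)")
  f <- eval_poly(cfg$dispersion_coeffs, seq_len(cfg$n_px) - 1)
  if (spec$nu_b_ghz > max(f) || -spec$nu_b_ghz < min(f))
    stop("Brillouin peaks fall outside the detector")
  step <- max(abs(diff(f)))
  el_fwhm <- max(cfg$instrument_fwhm_ghz, step)
  br_fwhm <- spec$gamma_true_ghz + cfg$instrument_fwhm_ghz
  clean <- cfg$baseline +
    cfg$elastic_amplitude * lorentz(f, 0, el_fwhm) +
    cfg$brillouin_amplitude * (lorentz(f, -spec$nu_b_ghz, br_fwhm) +
                               lorentz(f, +spec$nu_b_ghz, br_fwhm))
  counts <- switch(cfg$noise_model,
    none = clean,
    poisson = withr::with_seed(cfg$seed, stats::rpois(length(clean), clean)),
    gaussian = withr::with_seed(cfg$seed,
      pmax(clean + stats::rnorm(length(clean), 0, cfg$noise_sigma), 0)))
  gt <- list(spec = spec, measured_fwhm_ghz = br_fwhm, clean = clean)
  out <- brillouin_spectrum(counts, cfg$dispersion_coeffs, cfg$fsr_ghz,
                            ground_truth = gt)
  ## separability: peak centres must be > one combined half-width apart
  if (spec$nu_b_ghz < (br_fwhm + el_fwhm))
    attr(out, "overlap_warning") <- TRUE
  out
}

#' Population description of a simulated cohort
#'
#' Per-parameter normal population means and SDs emulating one exposure
#' condition; draws are truncated to physical ranges at generation.
#'
#' @param n_cells Number of cells (>= 0).
#' @param condition Condition label.
#' @param diameter_um,n_cell,nu_b_ghz,gamma_b_ghz Length-2 numeric vectors
#'   c(mean, sd) of the population distributions. Defaults are the control
#'   condition of the validation experiment.
#' @param seed RNG seed for the cohort draw.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_cells = 21L, condition = "control",
                        diameter_um = c(12.9, 1.8),
                        n_cell = c(1.371, 0.005),
                        nu_b_ghz = c(7.865, 0.049),
                        gamma_b_ghz = c(1.279, 0.072),
                        seed = 1L) {
  stopifnot(n_cells >= 0,
            all(vapply(list(diameter_um, n_cell, nu_b_ghz, gamma_b_ghz),
                       function(x) length(x) == 2 && x[2] >= 0, logical(1))))
  structure(list(n_cells = as.integer(n_cells), condition = condition,
                 diameter_um = diameter_um, n_cell = n_cell,
                 nu_b_ghz = nu_b_ghz, gamma_b_ghz = gamma_b_ghz,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Built-in cohort presets for the three exposure conditions
#'
#' Population means and SDs for the control, microtubule-disrupted
#' (nocodazole) and hypoosmotic-shock conditions used throughout the tests.
#'
#' @param condition One of "control", "nocodazole", "hypoosmotic".
#' @param seed RNG seed passed to \code{\link{cohort_spec}}.
#' @return A \code{\link{cohort_spec}}.
#' @export
cohort_preset <- function(condition = c("control", "nocodazole", "hypoosmotic"),
                          seed = 1L) {
  condition <- match.arg(condition)
  switch(condition,
    control = cohort_spec(21L, "control", c(12.9, 1.8), c(1.371, 0.005),
                          c(7.865, 0.049), c(1.279, 0.072), seed = seed),
    nocodazole = cohort_spec(25L, "nocodazole", c(13.5, 1.7), c(1.367, 0.007),
                             c(7.904, 0.084), c(1.281, 0.085), seed = seed),
    hypoosmotic = cohort_spec(26L, "hypoosmotic", c(14.5, 1.7), c(1.361, 0.007),
                              c(7.687, 0.145), c(1.038, 0.161), seed = seed))
}

#' Draw per-cell ground-truth parameters for a cohort
#'
#' Draws (diameter, n_cell, nu_B, Gamma_B) per cell from the cohort's normal
#' populations, truncated to physical ranges (positive diameter and
#' linewidth, n_cell >= n_medium, 0 < nu_B < FSR/2) by redrawing.
#' Deterministic under the cohort seed.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param n_medium Medium refractive index used as the lower truncation for
#'   \code{n_cell}.
#' @param fsr_ghz Free spectral range bounding \code{nu_b_ghz}.
#' @return A data.frame with one row per cell.
#' @export
draw_cohort_params <- function(spec, n_medium = 1.335, fsr_ghz = 29.95) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cells
  if (n == 0)
    return(data.frame(cell = integer(0), condition = character(0),
                      diameter_um = numeric(0), n_cell = numeric(0),
                      nu_b_ghz = numeric(0), gamma_b_ghz = numeric(0)))
  draw_trunc <- function(n, ms, lo, hi) {
    x <- stats::rnorm(n, ms[1], ms[2])
    for (k in seq_len(200)) {
      bad <- x <= lo | x >= hi
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), ms[1], ms[2])
    }
    pmin(pmax(x, lo + 1e-9), hi - 1e-9)
  }
  withr::with_seed(spec$seed, {
    data.frame(cell = seq_len(n), condition = spec$condition,
               diameter_um = draw_trunc(n, spec$diameter_um, 0, Inf),
               n_cell = draw_trunc(n, spec$n_cell, n_medium, Inf),
               nu_b_ghz = draw_trunc(n, spec$nu_b_ghz, 0, fsr_ghz / 2),
               gamma_b_ghz = draw_trunc(n, spec$gamma_b_ghz, 0, Inf),
               stringsAsFactors = FALSE)
  })
}

#' Generate a seeded cohort of paired hologram + spectrum simulations
#'
#' Draws per-cell parameters with \code{\link{draw_cohort_params}} and
#' renders, for each cell, the off-axis interferogram and the Brillouin
#' spectrum. Per-cell seeds are derived from the cohort seed so the whole
#' cohort is reproducible.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param hcfg A \code{\link{hologram_sim_config}} template.
#' @param scfg A \code{\link{spectrum_sim_config}} template.
#' @param consts A \code{\link{physical_constants}} (for \code{n_medium}).
#' @return A list of cells; each element has \code{interferogram},
#'   \code{spectrum}, \code{truth} (one-row data.frame) and \code{condition}.
#' @export
make_cohort <- function(spec, hcfg = hologram_sim_config(),
                        scfg = spectrum_sim_config(),
                        consts = physical_constants()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pars <- draw_cohort_params(spec, n_medium = consts$n_medium,
                             fsr_ghz = scfg$fsr_ghz)
  ## intrinsic linewidth must stay positive after instrument broadening is
  ## added at simulation and subtracted at analysis
  lapply(seq_len(nrow(pars)), function(i) {
    p <- pars[i, ]
    cell <- synthetic_cell_spec(diameter_um = p$diameter_um,
                                n_cell = p$n_cell,
                                n_medium = consts$n_medium,
                                nu_b_ghz = p$nu_b_ghz,
                                gamma_true_ghz = p$gamma_b_ghz)
    seed_i <- (spec$seed + 7919L * i) %% .Machine$integer.max
    hcfg_i <- hcfg; hcfg_i$seed <- seed_i
    scfg_i <- scfg; scfg_i$seed <- seed_i
    ph <- simulate_phase_object(cell, hcfg_i)
    list(interferogram = simulate_interferogram(ph, hcfg_i),
         spectrum = simulate_brillouin_spectrum(cell, scfg_i),
         truth = p, condition = spec$condition)
  })
}
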