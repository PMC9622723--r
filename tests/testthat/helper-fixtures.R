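## Shared fixtures, computed lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

## Noise-free, blur-free hologram config at study pitch (0.1 um/px).
clean_hcfg <- function(...) {
  hologram_sim_config(blur_sigma_px = 0, noise_sigma = 0, ...)
}

## Noise-free config with the PSF blur that the 1.08 divisor compensates.
blurred_hcfg <- function(...) {
  hologram_sim_config(blur_sigma_px = 6, noise_sigma = 0, ...)
}

## Noise-free spectrum config.
clean_scfg <- function(...) {
  spectrum_sim_config(noise_model = "none", ...)
}

## A clean simulated sphere phase map (D = 12 um, dn = 0.040).
clean_sphere_phase <- function() {
  fixture("clean_sphere_phase", {
    simulate_phase_object(
      synthetic_cell_spec(diameter_um = 12, n_cell = 1.375), clean_hcfg())
  })
}

## Interferogram of the clean sphere.
clean_sphere_interf <- function() {
  fixture("clean_sphere_interf", {
    simulate_interferogram(clean_sphere_phase(), clean_hcfg())
  })
}

## Grid radius (um) from the field centre, matching default 256 px config.
radius_grid_um <- function(n = 256, pixel_um = 0.1) {
  cen <- (n - 1) / 2
  sqrt(outer(((0:(n - 1)) - cen)^2, ((0:(n - 1)) - cen)^2, "+")) * pixel_um
}

## Hand-built sphere fit for geometry arithmetic tests.
manual_sphere_fit <- function(diameter_um, center_px = c(127.5, 127.5),
                              pixel_um = 0.1, calibration_factor = 1) {
  structure(list(center_px = center_px,
                 diameter_raw_um = diameter_um * calibration_factor,
                 diameter_um = diameter_um,
                 calibration_factor = calibration_factor,
                 accumulator_score = 1, pixel_um = pixel_um),
            class = "sphere_fit")
}
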