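#' Physical constants for biophysical parameter computation
#'
#' Bundles the material and instrument constants that convert a phase map and
#' a Brillouin spectrum into biophysical quantities. Units are a coherent
#' micro-scale set: lengths in micrometres, masses in picograms, frequencies
#' in gigahertz, wavelengths in nanometres. Note the exact identity
#' 1 mL/g = 1 um^3/pg, so densities in g/mL and pg/um^3 are numerically equal.
#'
#' @param alpha_ml_per_g Refractive-index increment of intracellular protein
#'   (mL/g). Near-universal across biomolecules; default 0.2.
#' @param rho_dry Mass density of the dry (protein-like) component
#'   (pg/um^3 = g/mL); default 1.37.
#' @param rho_fluid Mass density of the fluid (water-like) component
#'   (pg/um^3 = g/mL); default 1.0.
#' @param n_medium Refractive index of the imaging medium; default 1.335.
#' @param lambda_q_nm Phase-imaging illumination wavelength (nm); default 632.8.
#' @param lambda_b_nm Brillouin excitation wavelength (nm); default 532.
#' @param instrument_fwhm_ghz FWHM of the spectrometer instrument response
#'   (GHz), subtracted linearly from fitted Brillouin linewidths;
#'   default 0.398.
#' @param fsr_ghz Free spectral range of the VIPA etalon (GHz); default 29.95.
#' @param hough_calibration Dimensionless divisor applied to the raw Hough
#'   diameter, compensating the systematic overestimate caused by the
#'   objective's point-spread blur; default 1.08 (an ~8\% bias measured on
#'   10 um bead standards).
#' @return An object of class \code{physical_constants} (a named list).
#' @examples
#' pc <- physical_constants()
#' pc$alpha_ml_per_g
#' @export
physical_constants <- function(alpha_ml_per_g = 0.2,
                               rho_dry = 1.37,
                               rho_fluid = 1.0,
                               n_medium = 1.335,
                               lambda_q_nm = 632.8,
                               lambda_b_nm = 532,
                               instrument_fwhm_ghz = 0.398,
                               fsr_ghz = 29.95,
                               hough_calibration = 1.08) {
  vals <- list(alpha_ml_per_g = alpha_ml_per_g, rho_dry = rho_dry,
               rho_fluid = rho_fluid, n_medium = n_medium,
               lambda_q_nm = lambda_q_nm, lambda_b_nm = lambda_b_nm,
               instrument_fwhm_ghz = instrument_fwhm_ghz, fsr_ghz = fsr_ghz,
               hough_calibration = hough_calibration)
  num <- vapply(vals[1:8], function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))
  if (!all(num)) stop("all physical constants must be single positive finite numbers")
  if (rho_dry <= rho_fluid) stop("rho_dry must exceed rho_fluid")
  structure(vals, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

## Centralized unit handbook (tested): g/mL -> kg/m^3, GHz -> Hz, nm -> m,
## Pa -> GPa. Kept as constants so every formula uses the same conversions.
.G_PER_ML_TO_KG_M3 <- 1e3
.GHZ_TO_HZ <- 1e9
.NM_TO_M <- 1e-9
.PA_TO_GPA <- 1e-9
.NM_TO_UM <- 1e-3
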