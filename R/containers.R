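## Lightweight S3 containers shared across the pipeline stages.

#' Interferogram container
#'
#' A raw off-axis interferogram: a 2-D non-negative intensity array together
#' with the pixel pitch and illumination wavelength needed to interpret it.
#'
#' @param pixels Numeric matrix of non-negative intensities (camera counts).
#' @param pixel_um Pixel pitch in the sample plane (um/px).
#' @param lambda_q_nm Illumination wavelength (nm).
#' @param ground_truth Optional list carrying simulation ground truth.
#' @return Object of class \code{interferogram}.
#' @export
interferogram <- function(pixels, pixel_um, lambda_q_nm, ground_truth = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("interferogram intensities must be finite and non-negative")
  if (!is.numeric(pixel_um) || pixel_um <= 0) stop("pixel_um must be > 0")
  structure(list(pixels = pixels, pixel_um = pixel_um,
                 lambda_q_nm = lambda_q_nm, ground_truth = ground_truth),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("Interferogram %d x %d px, %.3g um/px, lambda %g nm\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_um, x$lambda_q_nm))
  invisible(x)
}

#' Phase map container
#'
#' Optical phase phi(x, y) in radians on a calibrated pixel grid, optionally
#' with a logical cell mask. This is the product of demodulation +
#' unwrapping + background removal that all downstream stages consume.
#'
#' @param phi Numeric matrix of phase values (radians).
#' @param pixel_um Pixel pitch (um/px).
#' @param lambda_q_nm Illumination wavelength (nm).
#' @param mask Optional logical matrix marking cell pixels.
#' @param ground_truth Optional list carrying simulation ground truth.
#' @return Object of class \code{phase_map}.
#' @export
phase_map <- function(phi, pixel_um, lambda_q_nm, mask = NULL,
                      ground_truth = NULL) {
  stopifnot(is.matrix(phi), is.numeric(phi))
  if (any(!is.finite(phi))) stop("phase must be finite everywhere")
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask), identical(dim(mask), dim(phi)))
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  }
  structure(list(phi = phi, pixel_um = pixel_um, lambda_q_nm = lambda_q_nm,
                 mask = mask, ground_truth = ground_truth),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("PhaseMap %d x %d px, %.3g um/px, range [%.3f, %.3f] rad%s\n",
              nrow(x$phi), ncol(x$phi), x$pixel_um,
              min(x$phi), max(x$phi),
              if (is.null(x$mask)) "" else sprintf(", mask %d px", sum(x$mask))))
  invisible(x)
}

#' Complex field container
#'
#' The demodulated complex field whose argument is the wrapped optical phase.
#'
#' @param values Complex matrix.
#' @param pixel_um Pixel pitch (um/px).
#' @param lambda_q_nm Illumination wavelength (nm).
#' @param carrier Detected carrier frequency (cycles/field, length-2).
#' @return Object of class \code{complex_field}.
#' @export
complex_field <- function(values, pixel_um, lambda_q_nm, carrier = NULL) {
  stopifnot(is.matrix(values), is.complex(values))
  if (any(!is.finite(values))) stop("complex field must be finite")
  structure(list(values = values, pixel_um = pixel_um,
                 lambda_q_nm = lambda_q_nm, carrier = carrier),
            class = "complex_field")
}

#' Brillouin spectrum container
#'
#' A 1-D spectrum of detector counts versus pixel, plus the dispersion
#' polynomial mapping pixel index (0-based) to frequency in GHz and the
#' free spectral range of the etalon.
#'
#' @param counts Numeric vector of non-negative counts.
#' @param dispersion_coeffs Polynomial coefficients c0, c1, ... such that
#'   GHz = sum(c_k * px^k) with px the 0-based pixel index. Must be strictly
#'   monotone over the support.
#' @param fsr_ghz Free spectral range (GHz).
#' @param ground_truth Optional list carrying simulation ground truth.
#' @return Object of class \code{brillouin_spectrum}.
#' @export
brillouin_spectrum <- function(counts, dispersion_coeffs, fsr_ghz,
                               ground_truth = NULL) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (fsr_ghz <= 0) stop("fsr_ghz must be > 0")
  f <- eval_poly(dispersion_coeffs, seq_along(counts) - 1)
  if (any(diff(f) <= 0) && any(diff(f) >= 0) && !(all(diff(f) > 0) || all(diff(f) < 0)))
    stop("dispersion must be strictly monotone over the pixel range")
  if (any(diff(f) == 0)) stop("dispersion must be strictly monotone over the pixel range")
  structure(list(counts = counts, dispersion_coeffs = dispersion_coeffs,
                 fsr_ghz = fsr_ghz, ground_truth = ground_truth),
            class = "brillouin_spectrum")
}

#' @export
print.brillouin_spectrum <- function(x, ...) {
  f <- ghz_axis(x)
  cat(sprintf("BrillouinSpectrum %d px, axis [%.2f, %.2f] GHz, FSR %.2f GHz\n",
              length(x$counts), min(f), max(f), x$fsr_ghz))
  invisible(x)
}

#' Frequency axis of a Brillouin spectrum
#'
#' @param spectrum A \code{brillouin_spectrum}.
#' @return Numeric vector of frequencies (GHz), one per detector pixel.
#' @export
ghz_axis <- function(spectrum) {
  eval_poly(spectrum$dispersion_coeffs, seq_along(spectrum$counts) - 1)
}

## Evaluate a polynomial with coefficients c0, c1, ... at x (Horner).
eval_poly <- function(coeffs, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coeffs))) out <- out * x + coeffs[[k]]
  out
}
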