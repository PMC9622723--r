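## Brillouin spectrum analysis: FSR-anchored pixel->GHz calibration,
## Lorentzian least-squares peak fits, half-distance shift, linewidth
## correction for the instrument response, and spectral SNR.

#' Calibrate the pixel-to-GHz dispersion from elastic-order positions
#'
#' Consecutive elastic orders of the etalon are one free spectral range
#' apart; given the pixel positions of two or more adjacent orders, fits a
#' polynomial (linear for two anchors, quadratic for three or more) mapping
#' pixel to GHz, with the frequency origin at the chosen anchor.
#'
#' @param elastic_peak_pixels Pixel positions (0-based, sub-pixel allowed)
#'   of adjacent elastic orders, in increasing order.
#' @param fsr_ghz Free spectral range (GHz).
#' @param origin Index (into \code{elastic_peak_pixels}) of the order that
#'   defines 0 GHz; default 1.
#' @return Numeric dispersion coefficients c0, c1, ... (GHz as a polynomial
#'   in the 0-based pixel index).
#' @examples
#' co <- pixel_to_ghz(c(100, 900), fsr_ghz = 29.95)
#' sum(co * c(1, 500))  # 14.975 GHz at pixel 500
#' @export
pixel_to_ghz <- function(elastic_peak_pixels, fsr_ghz = 29.95, origin = 1L) {
  px <- as.numeric(elastic_peak_pixels)
  if (length(px) < 2) stop("need at least two elastic-order positions")
  if (any(duplicated(px))) stop("elastic-order anchor pixels must be distinct")
  if (is.unsorted(px)) stop("anchor pixels must be increasing")
  ghz <- (seq_along(px) - origin) * fsr_ghz
  deg <- min(length(px) - 1, 2)
  fit <- stats::lm(ghz ~ stats::poly(px, degree = deg, raw = TRUE))
  co <- unname(stats::coef(fit))
  co[is.na(co)] <- 0
  co
}

## Initial Lorentzian parameters from a local maximum and its half-max
## crossings. x, y restricted to the fit window.
lorentz_init <- function(x, y) {
  off <- min(y)
  amp <- max(y) - off
  ctr <- x[which.max(y)]
  half <- off + amp / 2
  above <- y >= half
  i0 <- which.max(y)
  lo <- i0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  fwhm <- abs(x[hi] - x[lo])
  if (fwhm <= 0) fwhm <- 2 * min(diff(sort(x)))
  list(amp = amp, ctr = ctr, fwhm = fwhm, off = off)
}

#' Fit a single Lorentzian peak by least squares
#'
#' Model: L(f) = A (G/2)^2 / ((f - c)^2 + (G/2)^2) + offset, fitted with
#' Levenberg-Marquardt least squares; initialized from the window maximum
#' and its half-maximum crossings.
#'
#' @param f Frequency axis (GHz) of the fit window.
#' @param counts Counts over the fit window.
#' @return Object of class \code{lorentzian_peak}: \code{center_ghz},
#'   \code{fwhm_ghz}, \code{amplitude}, \code{offset}, \code{resid_norm}.
#' @export
fit_lorentzian <- function(f, counts) {
  stopifnot(length(f) == length(counts), length(f) >= 5)
  ini <- lorentz_init(f, counts)
  resid_fn <- function(p) {
    counts - (p[1] * (p[3] / 2)^2 / ((f - p[2])^2 + (p[3] / 2)^2) + p[4])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(ini$amp, ini$ctr, ini$fwhm, ini$off),
      lower = c(0, min(f), 1e-6, -Inf),
      upper = c(Inf, max(f), diff(range(f)) * 4, Inf),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || fit$info %in% c(0, 5, 9))
    stop(sprintf("Lorentzian fit did not converge: %s (window %.2f..%.2f GHz, residual of init %.3g)",
                 if (inherits(fit, "error")) conditionMessage(fit) else fit$message,
                 min(f), max(f),
                 sqrt(mean(resid_fn(c(ini$amp, ini$ctr, ini$fwhm, ini$off))^2))))
  p <- fit$par
  structure(list(center_ghz = p[2], fwhm_ghz = p[3],
                 amplitude = p[1], offset = p[4],
                 resid_norm = sqrt(fit$deviance)),
            class = "lorentzian_peak")
}

## Local maxima with a simple prominence measure.
find_peaks <- function(y, min_prominence, halfwin = 3L) {
  n <- length(y)
  idx <- integer(0)
  for (i in seq(halfwin + 1, n - halfwin)) {
    win <- y[(i - halfwin):(i + halfwin)]
    if (y[i] == max(win) && y[i] > y[i - 1]) {
      ## prominence: height above the higher of the two valley minima
      left <- y[1:i]; right <- y[i:n]
      hl <- which(left > y[i]); hr <- which(right > y[i])
      vl <- if (length(hl)) min(left[max(hl):i]) else min(left)
      vr <- if (length(hr)) min(right[1:min(hr)]) else min(right)
      if (y[i] - max(vl, vr) >= min_prominence) idx <- c(idx, i)
    }
  }
  idx
}

#' Locate and fit the elastic and Brillouin peaks of a spectrum
#'
#' Peaks are located by local-maximum search with a prominence threshold on
#' the calibrated GHz axis; the elastic line is the most prominent peak
#' nearest 0 GHz, the Stokes and anti-Stokes peaks the strongest candidates
#' below and above it. Each peak is fitted independently over a window of
#' about 3x its half-power width (clipped at the midpoint to its
#' neighbour).
#'
#' @param spectrum A \code{\link{brillouin_spectrum}}.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   spectrum's dynamic range (default 0.02).
#' @param window_factor Fit window half-width as a multiple of the estimated
#'   FWHM (default 1.5, i.e. a full window of 3 FWHM).
#' @return List with \code{lorentzian_peak} elements \code{stokes},
#'   \code{antistokes}, \code{elastic}.
#' @export
locate_and_fit_peaks <- function(spectrum, prominence_frac = 0.02,
                                 window_factor = 1.5) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  f <- ghz_axis(spectrum)
  y <- spectrum$counts
  rng <- diff(range(y))
  if (rng <= 0) stop("peak not found: flat spectrum")
  cand <- find_peaks(y, min_prominence = prominence_frac * rng)
  if (length(cand) == 0) stop("peak not found: no prominent local maxima")
  fc <- f[cand]
  el_i <- cand[which.min(abs(fc))]
  if (abs(f[el_i]) > 1) stop("peak not found: no elastic line near 0 GHz")
  stokes_cand <- cand[fc < f[el_i] - 1]
  anti_cand <- cand[fc > f[el_i] + 1]
  if (length(stokes_cand) == 0) stop("peak not found: Stokes peak missing")
  if (length(anti_cand) == 0) stop("peak not found: anti-Stokes peak missing")
  st_i <- stokes_cand[which.max(y[stokes_cand])]
  an_i <- anti_cand[which.max(y[anti_cand])]
  fit_one <- function(i, neighbours) {
    ini <- lorentz_init(f, y)  # global init only for scale; window below
    ## half-power width estimate around i
    half <- (y[i] + stats::median(y)) / 2
    lo <- i; while (lo > 1 && y[lo] > half) lo <- lo - 1
    hi <- i; while (hi < length(y) && y[hi] > half) hi <- hi + 1
    hw_ghz <- window_factor * max(abs(f[hi] - f[lo]), 4 * max(abs(diff(f))))
    lo_f <- f[i] - hw_ghz; hi_f <- f[i] + hw_ghz
    ## clip at midpoints to neighbouring peaks
    for (j in neighbours) {
      if (f[j] < f[i]) lo_f <- max(lo_f, (f[i] + f[j]) / 2)
      if (f[j] > f[i]) hi_f <- min(hi_f, (f[i] + f[j]) / 2)
    }
    sel <- f >= lo_f & f <= hi_f
    list(sel = sel, fit = fit_lorentzian(f[sel], y[sel]))
  }
  st <- fit_one(st_i, c(el_i, an_i))
  an <- fit_one(an_i, c(el_i, st_i))
  el <- fit_one(el_i, c(st_i, an_i))
  ## one refinement pass: refit each peak on the counts minus the fitted
  ## tails of its neighbours, removing the bias their slopes induce
  tail_of <- function(p) p$amplitude * lorentz(f, p$center_ghz, p$fwhm_ghz)
  refit <- function(this, others) {
    y2 <- y - Reduce(`+`, lapply(others, tail_of))
    fit_lorentzian(f[this$sel], y2[this$sel])
  }
  list(stokes = refit(st, list(an$fit, el$fit)),
       antistokes = refit(an, list(st$fit, el$fit)),
       elastic = refit(el, list(st$fit, an$fit)))
}

#' Brillouin shift from the fitted peak pair
#'
#' Half the distance between the Stokes and anti-Stokes peak centres on the
#' GHz axis; invariant under a global frequency offset.
#'
#' @param stokes,antistokes \code{lorentzian_peak} fits.
#' @return Shift nu_B in GHz. A zero separation is flagged with a warning.
#' @export
brillouin_shift <- function(stokes, antistokes) {
  nu <- abs(antistokes$center_ghz - stokes$center_ghz) / 2
  if (nu == 0) warning("coincident Stokes/anti-Stokes centers: implausible zero shift")
  nu
}

#' Correct a fitted linewidth for instrument broadening
#'
#' Linear subtraction of the instrument response FWHM from the measured
#' (fitted) FWHM.
#'
#' @param gamma_measured_ghz Fitted FWHM (GHz).
#' @param instrument_fwhm_ghz Instrument response FWHM (GHz).
#' @return Corrected linewidth Gamma_B (GHz); errors if the result is not
#'   positive.
#' @export
correct_linewidth <- function(gamma_measured_ghz, instrument_fwhm_ghz = 0.398) {
  stopifnot(instrument_fwhm_ghz >= 0)
  out <- gamma_measured_ghz - instrument_fwhm_ghz
  if (out <= 0) stop("linewidth below instrument response")
  out
}

#' Spectral signal-to-noise ratio in dB
#'
#' 10 log10 of the mean fitted Brillouin peak amplitude over the standard
#' deviation of the counts in a peak-free window (pixels farther than
#' \code{exclusion_fwhm} fitted widths from every peak centre). This is the
#' package's operational SNR definition. A noise-free spectrum (zero
#' residual SD) is capped at \code{cap_db}.
#'
#' @param spectrum A \code{\link{brillouin_spectrum}}.
#' @param peaks Result of \code{\link{locate_and_fit_peaks}}.
#' @param exclusion_fwhm Multiples of each peak's FWHM excluded around its
#'   centre (default 3).
#' @param cap_db Cap for degenerate noise-free spectra (default 99).
#' @return SNR in dB.
#' @export
spectrum_snr <- function(spectrum, peaks, exclusion_fwhm = 3, cap_db = 99) {
  f <- ghz_axis(spectrum)
  y <- spectrum$counts
  keep <- rep(TRUE, length(f))
  for (p in peaks[c("stokes", "antistokes", "elastic")]) {
    keep <- keep & abs(f - p$center_ghz) > exclusion_fwhm * p$fwhm_ghz
  }
  if (!any(keep)) stop("no peak-free window for noise estimation")
  ## residuals against the full fitted model (three Lorentzians plus a
  ## median-matched baseline), with a successive-difference SD estimate to
  ## stay insensitive to any remaining smooth trend
  model <- rep(0, length(f))
  for (p in peaks[c("stokes", "antistokes", "elastic")])
    model <- model + p$amplitude * lorentz(f, p$center_ghz, p$fwhm_ghz)
  model <- model + stats::median(y[keep] - model[keep])
  yw <- (y - model)[keep]
  runs <- split(yw, cumsum(c(1, diff(which(keep)) != 1)))
  d <- unlist(lapply(runs, function(r) if (length(r) > 1) diff(r) else NULL))
  if (is.null(d) || length(d) < 2) stop("no peak-free window for noise estimation")
  amp <- mean(c(peaks$stokes$amplitude, peaks$antistokes$amplitude))
  sdres <- sqrt(mean(d^2) / 2)
  ## residuals at numerical-noise level mean a noise-free spectrum
  if (sdres <= amp * 1e-8) return(cap_db)
  min(10 * log10(amp / sdres), cap_db)
}

#' Percent change between two measurements
#'
#' 100 (after - before) / before; errors when \code{before} is zero.
#'
#' @param before,after Numeric scalars.
#' @return Percent change.
#' @examples
#' relative_change(8.407, 8.172)  # -2.8 (percent)
#' @export
relative_change <- function(before, after) {
  if (before == 0) stop("reference value is zero")
  100 * (after - before) / before
}

#' Full Brillouin spectrum analysis
#'
#' Locates and fits the peaks, computes the shift (half-distance rule), the
#' instrument-corrected linewidth (mean of the Stokes and anti-Stokes
#' fitted FWHMs, minus the instrument response), and the SNR.
#'
#' @param spectrum A \code{\link{brillouin_spectrum}}.
#' @param instrument_fwhm_ghz Instrument response FWHM (GHz).
#' @param ... Passed to \code{\link{locate_and_fit_peaks}}.
#' @return Object of class \code{brillouin_result}: \code{nu_b_ghz},
#'   \code{gamma_b_ghz}, \code{gamma_measured_ghz}, \code{snr_db},
#'   \code{stokes}, \code{antistokes}, \code{elastic}.
#' @export
analyze_spectrum <- function(spectrum, instrument_fwhm_ghz = 0.398, ...) {
  pk <- locate_and_fit_peaks(spectrum, ...)
  nu <- brillouin_shift(pk$stokes, pk$antistokes)
  gmeas <- mean(c(pk$stokes$fwhm_ghz, pk$antistokes$fwhm_ghz))
  gb <- correct_linewidth(gmeas, instrument_fwhm_ghz)
  structure(list(nu_b_ghz = nu, gamma_b_ghz = gb, gamma_measured_ghz = gmeas,
                 snr_db = spectrum_snr(spectrum, pk),
                 stokes = pk$stokes, antistokes = pk$antistokes,
                 elastic = pk$elastic),
            class = "brillouin_result")
}

#' @export
print.brillouin_result <- function(x, ...) {
  cat(sprintf(
    "BrillouinResult: nu_B %.3f GHz, Gamma_B %.3f GHz (measured %.3f), SNR %.1f dB\n",
    x$nu_b_ghz, x$gamma_b_ghz, x$gamma_measured_ghz, x$snr_db))
  invisible(x)
}
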