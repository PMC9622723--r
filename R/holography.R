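## Off-axis hologram -> phase map: Fourier sideband demodulation, 2-D
## least-squares phase unwrapping with an exact mod-2pi congruence step,
## polynomial background removal, and threshold-based cell segmentation.

#' Demodulate an off-axis interferogram
#'
#' Applies a 2-D FFT, auto-detects the carrier as the strongest spectral
#' peak outside a DC exclusion disc (unless hinted), crops a window around
#' the sideband, recentres it to zero frequency and inverse-transforms. The
#' argument of the returned field is the wrapped object phase.
#'
#' @param interf An \code{\link{interferogram}}.
#' @param sideband_hint Optional length-2 carrier frequency (cycles/field,
#'   signed, row then column) to skip auto-detection.
#' @param crop_frac Half-width of the crop window as a fraction of the
#'   smaller spectrum dimension (default 1/8). The window is additionally
#'   limited so it cannot reach the DC term.
#' @param taper_frac Radial fraction of the crop window that is passed
#'   unattenuated; beyond it a raised-cosine (Tukey) taper rolls off to the
#'   window edge, suppressing truncation ringing. Set to 1 for a hard crop.
#' @param window Apply a Hann window before the FFT (useful for real data
#'   whose fringes are not periodic across the frame); default FALSE.
#' @return A \code{\link{complex_field}} whose \code{Arg()} is the wrapped
#'   phase (in (-pi, pi]).
#' @export
demodulate <- function(interf, sideband_hint = NULL, crop_frac = 1 / 8,
                       taper_frac = 0.6, window = FALSE) {
  stopifnot(taper_frac > 0, taper_frac <= 1)
  stopifnot(inherits(interf, "interferogram"))
  I <- interf$pixels
  nr <- nrow(I); nc <- ncol(I)
  if (window) {
    hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    I <- I * outer(hann(nr), hann(nc))
  }
  F <- stats::fft(I)
  fr <- ifelse(0:(nr - 1) > nr / 2, 0:(nr - 1) - nr, 0:(nr - 1))
  fc <- ifelse(0:(nc - 1) > nc / 2, 0:(nc - 1) - nc, 0:(nc - 1))
  if (is.null(sideband_hint)) {
    P <- Mod(F)
    excl <- max(3, ceiling(min(nr, nc) / 16))
    rad <- sqrt(outer(fr^2, fc^2, "+"))
    P[rad <= excl] <- 0
    thr <- 10 * stats::median(P[rad > excl])
    if (max(P) <= thr) stop("no carrier detected")
    idx <- arrayInd(which.max(P), dim(P))
    pk <- c(fr[idx[1]], fc[idx[2]])
  } else {
    pk <- sideband_hint
  }
  ## deterministic sign convention: keep the positive-frequency sideband
  if (pk[1] < 0 || (pk[1] == 0 && pk[2] < 0)) pk <- -pk
  w <- floor(crop_frac * min(nr, nc))
  ## the square window must never reach the DC term (Chebyshev distance)
  w <- min(w, max(2, max(abs(pk)) - 1))
  ## build recentred cropped spectrum: for offsets (dr, dc) in [-w, w],
  ## G[dr, dc] = F[pk + (dr, dc)]
  idx_of <- function(f, n) ((f %% n) + 1)
  G <- matrix(0 + 0i, nr, nc)
  dr <- -w:w; dc <- -w:w
  src_r <- idx_of(pk[1] + dr, nr); src_c <- idx_of(pk[2] + dc, nc)
  dst_r <- idx_of(dr, nr); dst_c <- idx_of(dc, nc)
  blk <- F[src_r, src_c]
  if (taper_frac < 1) {
    rad <- sqrt(outer(dr^2, dc^2, "+")) / w
    tap <- ifelse(rad >= 1, 0,
                  ifelse(rad <= taper_frac, 1,
                         0.5 * (1 + cos(pi * (rad - taper_frac) /
                                        (1 - taper_frac)))))
    blk <- blk * tap
  }
  G[dst_r, dst_c] <- blk
  field <- stats::fft(G, inverse = TRUE) / length(G)
  ## +f_c sideband of cos(carrier - phi) carries exp(-i phi): conjugate so
  ## that Arg(field) = +phi under the recording convention
  field <- Conj(field)
  complex_field(field, interf$pixel_um, interf$lambda_q_nm, carrier = pk)
}

## Wrap to (-pi, pi].
wrap_phase <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

## Solve the Neumann Poisson problem lap(phi) = rho on a grid via
## even mirror extension + FFT (equivalent to a DCT solve).
poisson_solve_neumann <- function(rho) {
  nr <- nrow(rho); nc <- ncol(rho)
  E <- rbind(cbind(rho, rho[, nc:1]), cbind(rho[nr:1, ], rho[nr:1, nc:1]))
  Nr <- 2 * nr; Nc <- 2 * nc
  eig <- outer(2 * cos(2 * pi * (0:(Nr - 1)) / Nr) - 2,
               2 * cos(2 * pi * (0:(Nc - 1)) / Nc) - 2, "+")
  Fh <- stats::fft(E) / eig
  Fh[1, 1] <- 0
  out <- Re(stats::fft(Fh, inverse = TRUE)) / (Nr * Nc)
  out[seq_len(nr), seq_len(nc)]
}

#' Unwrap a 2-D wrapped phase
#'
#' Residue-safe two-dimensional unwrapping: a weighted least-squares
#' (Poisson) estimate from wrapped phase gradients, followed by a congruence
#' step that rounds the estimate back onto the lattice wrapped + 2 pi k.
#' The output is therefore congruent to the input modulo 2 pi at every
#' pixel, exactly. A residue count (non-zero loop integrals of the wrapped
#' gradient field) is attached as attribute \code{n_residues}; non-zero
#' residues flag possible unwrapping ambiguity.
#'
#' @param x A \code{\link{complex_field}}, a \code{\link{phase_map}} holding
#'   wrapped phase, or a numeric matrix of wrapped phase in (-pi, pi].
#' @param pixel_um,lambda_q_nm Grid metadata, required only when \code{x} is
#'   a bare matrix.
#' @return A \code{\link{phase_map}} with the unwrapped phase.
#' @export
unwrap <- function(x, pixel_um = NULL, lambda_q_nm = NULL) {
  gt <- NULL
  if (inherits(x, "complex_field")) {
    psi <- Arg(x$values); pixel_um <- x$pixel_um; lambda_q_nm <- x$lambda_q_nm
  } else if (inherits(x, "phase_map")) {
    psi <- x$phi; pixel_um <- x$pixel_um; lambda_q_nm <- x$lambda_q_nm
    gt <- x$ground_truth
  } else {
    stopifnot(is.matrix(x), !is.null(pixel_um), !is.null(lambda_q_nm))
    psi <- x
  }
  nr <- nrow(psi); nc <- ncol(psi)
  ## wrapped forward differences (Neumann: zero beyond the boundary)
  dx <- matrix(0, nr, nc); dy <- matrix(0, nr, nc)
  if (nc > 1) dx[, -nc] <- wrap_phase(psi[, -1] - psi[, -nc])
  if (nr > 1) dy[-nr, ] <- wrap_phase(psi[-1, ] - psi[-nr, ])
  ## residues: circulation of wrapped gradients around each 2x2 plaquette
  n_res <- 0L
  if (nr > 1 && nc > 1) {
    circ <- dx[-nr, -nc] + dy[-nr, -1] - dx[-1, -nc] - dy[-nr, -nc]
    n_res <- sum(abs(circ) > pi)
  }
  ## divergence of the wrapped gradient field
  rho <- dx - cbind(0, dx[, -nc, drop = FALSE]) +
         dy - rbind(0, dy[-nr, , drop = FALSE])
  ls <- poisson_solve_neumann(rho)
  out <- psi + 2 * pi * round((ls - psi) / (2 * pi))
  pm <- phase_map(out, pixel_um, lambda_q_nm, ground_truth = gt)
  attr(pm, "n_residues") <- n_res
  pm
}

#' Remove the smooth background phase
#'
#' Fits a 2-D polynomial (least squares) to the phase over non-cell pixels
#' and subtracts it everywhere, so the background median is approximately
#' zero. With \code{poly_order = 0} this reduces to subtracting the
#' background mean. The fit is idempotent: applying it twice changes the
#' phase only at numerical noise level.
#'
#' @param phase A \code{\link{phase_map}}.
#' @param mask Logical matrix marking cell pixels to exclude from the fit;
#'   defaults to the phase map's own mask, or no exclusion if none.
#' @param poly_order Total polynomial order (default 2).
#' @return A \code{\link{phase_map}} with background-subtracted phase (mask
#'   carried through).
#' @export
remove_background <- function(phase, mask = NULL, poly_order = 2) {
  stopifnot(inherits(phase, "phase_map"), poly_order >= 0)
  phi <- phase$phi
  if (is.null(mask)) mask <- phase$mask
  if (is.null(mask)) mask <- matrix(FALSE, nrow(phi), ncol(phi))
  bg_idx <- which(!mask)
  terms <- poly2d_terms(nrow(phi), ncol(phi), poly_order)
  if (length(bg_idx) < 10 * ncol(terms))
    stop("insufficient background pixels for polynomial fit")
  fit <- stats::lm.fit(terms[bg_idx, , drop = FALSE], phi[bg_idx])
  bg <- matrix(terms %*% fit$coefficients, nrow(phi), ncol(phi))
  phase_map(phi - bg, phase$pixel_um, phase$lambda_q_nm, mask = phase$mask,
            ground_truth = phase$ground_truth)
}

## Design matrix of 2-D polynomial terms u^i v^j, i + j <= order, on
## [-1, 1]-normalized coordinates (one row per pixel, column-major order).
poly2d_terms <- function(nr, nc, order) {
  u <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  v <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  U <- matrix(rep(u, nc), nr * nc)
  V <- matrix(rep(v, each = nr), nr * nc)
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i))
    cols[[length(cols) + 1]] <- U^i * V^j
  do.call(cbind, cols)
}

#' Segment the cell in a phase map
#'
#' Automated replacement for manual cropping: an Otsu threshold on the
#' phase locates candidate cell cores, the core with the largest integrated
#' phase is selected, and the mask is grown by hysteresis — the connected
#' region above a low threshold (a small fraction of the cell's peak phase)
#' that contains the selected core — so the full extent of the phase dome
#' is captured, not just its top. The result is morphologically closed.
#' The number of candidate cores is attached as attribute
#' \code{n_components}.
#'
#' @param phase A \code{\link{phase_map}} (background-dominant field).
#' @param min_area_px Minimum component area to count as a candidate cell.
#' @param low_frac Low hysteresis threshold, as a fraction of the selected
#'   component's peak phase (default 0.05).
#' @param close_size Diameter (px) of the disc brush used for morphological
#'   closing.
#' @return Logical matrix mask (TRUE = cell), with attribute
#'   \code{n_components}.
#' @export
segment_cell <- function(phase, min_area_px = 25L, low_frac = 0.05,
                         close_size = 5L) {
  stopifnot(inherits(phase, "phase_map"))
  phi <- phase$phi
  rng <- range(phi)
  if (diff(rng) <= .Machine$double.eps) stop("no cell found")
  norm <- (phi - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  labm <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg))))
  ids <- setdiff(unique(as.vector(labm)), 0)
  ids <- ids[vapply(ids, function(i) sum(labm == i), numeric(1)) >= min_area_px]
  if (length(ids) == 0) stop("no cell found")
  ## choose the core with the largest integrated phase
  scores <- vapply(ids, function(i) sum(phi[labm == i]), numeric(1))
  core <- labm == ids[which.max(scores)]
  ## hysteresis: keep the low-threshold component containing the core
  low <- low_frac * max(phi[core])
  lablo <- as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(phi > low))))
  core_label <- stats::median(lablo[core][lablo[core] > 0])
  mask <- lablo == core_label
  if (close_size > 1) {
    brush <- EBImage::makeBrush(close_size, shape = "disc")
    mask <- as.matrix(EBImage::imageData(
      EBImage::closing(EBImage::Image(mask * 1), brush))) > 0.5
  }
  attr(mask, "n_components") <- length(ids)
  mask
}
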