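## File IO: 16-bit TIFF interferograms, 32-bit float TIFF phase maps,
## 2-column CSV spectra, JSON sidecars for ground truth and fit results.

#' Write an interferogram as a 16-bit grayscale TIFF
#'
#' Metadata (pixel pitch, wavelength) and any simulation ground truth are
#' written to a JSON sidecar \code{<path>.json}.
#'
#' @param interf An \code{\link{interferogram}}.
#' @param path Output TIFF path.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_interferogram_tiff <- function(interf, path, sidecar = TRUE) {
  stopifnot(inherits(interf, "interferogram"))
  tiff::writeTIFF(interf$pixels / 65535, path, bits.per.sample = 16L)
  if (sidecar) {
    meta <- list(pixel_um = interf$pixel_um, lambda_q_nm = interf$lambda_q_nm)
    gt <- interf$ground_truth
    if (!is.null(gt$spec)) meta$ground_truth <- unclass(gt$spec)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a 16-bit TIFF interferogram
#'
#' @param path TIFF path; a sidecar \code{<path>.json} supplies pixel pitch
#'   and wavelength unless given explicitly.
#' @param pixel_um,lambda_q_nm Metadata overrides.
#' @return An \code{\link{interferogram}}.
#' @export
read_interferogram_tiff <- function(path, pixel_um = NULL,
                                    lambda_q_nm = NULL) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sc <- paste0(path, ".json")
  if ((is.null(pixel_um) || is.null(lambda_q_nm)) && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(pixel_um)) pixel_um <- meta$pixel_um
    if (is.null(lambda_q_nm)) lambda_q_nm <- meta$lambda_q_nm
  }
  if (is.null(pixel_um) || is.null(lambda_q_nm))
    stop("pixel_um and lambda_q_nm required (no JSON sidecar found)")
  interferogram(matrix(as.numeric(img), nrow(img), ncol(img)),
                pixel_um, lambda_q_nm)
}

#' Write a phase map as a 32-bit float TIFF
#'
#' Phase values are stored affinely rescaled to [0, 1] (TIFF float storage
#' here is defined on that range); the scaling and grid metadata go to a
#' JSON sidecar \code{<path>.json} so \code{\link{read_phase_tiff}} can
#' restore radians exactly.
#'
#' @param phase A \code{\link{phase_map}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phase_tiff <- function(phase, path) {
  stopifnot(inherits(phase, "phase_map"))
  lo <- min(phase$phi); hi <- max(phase$phi)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((phase$phi - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(phase_min = lo, phase_scale = scale,
                            pixel_um = phase$pixel_um,
                            lambda_q_nm = phase$lambda_q_nm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase map written by \code{\link{write_phase_tiff}}
#'
#' @param path TIFF path with its \code{<path>.json} sidecar.
#' @return A \code{\link{phase_map}}.
#' @export
read_phase_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  phase_map(matrix(img * meta$phase_scale + meta$phase_min,
                   nrow(img), ncol(img)),
            meta$pixel_um, meta$lambda_q_nm)
}

#' Read a cell mask from a PNG or TIFF file (nonzero = cell)
#'
#' @param path Image path (TIFF).
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Write a Brillouin spectrum as 2-column CSV (pixel, counts)
#'
#' Dispersion coefficients and FSR go to a JSON sidecar.
#'
#' @param spectrum A \code{\link{brillouin_spectrum}}.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, sidecar = TRUE) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  utils::write.csv(data.frame(pixel = seq_along(spectrum$counts) - 1,
                              counts = spectrum$counts),
                   path, row.names = FALSE)
  if (sidecar) {
    meta <- list(dispersion_coeffs = spectrum$dispersion_coeffs,
                 fsr_ghz = spectrum$fsr_ghz)
    gt <- spectrum$ground_truth
    if (!is.null(gt$spec)) meta$ground_truth <- unclass(gt$spec)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a Brillouin spectrum from CSV (or a TIFF camera frame)
#'
#' CSV input must have columns (pixel, counts). A 2-D TIFF frame is reduced
#' to 1-D by summing along the non-dispersive axis over an optional band of
#' rows or columns.
#'
#' @param path CSV or TIFF path.
#' @param dispersion_coeffs,fsr_ghz Calibration; read from the JSON sidecar
#'   \code{<path>.json} when omitted.
#' @param sum_axis For TIFF frames: 1 to sum over rows (dispersion along
#'   columns), 2 to sum over columns.
#' @param band Optional integer range of rows/columns to sum over.
#' @return A \code{\link{brillouin_spectrum}}.
#' @export
read_spectrum <- function(path, dispersion_coeffs = NULL, fsr_ghz = NULL,
                          sum_axis = 1L, band = NULL) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (!is.null(band)) {
      if (sum_axis == 1L) img <- img[band, , drop = FALSE]
      else img <- img[, band, drop = FALSE]
    }
    counts <- if (sum_axis == 1L) colSums(img) else rowSums(img)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("pixel", "counts") %in% names(df)))
      stop("spectrum CSV must have columns 'pixel' and 'counts'")
    counts <- df$counts[order(df$pixel)]
  }
  sc <- paste0(path, ".json")
  if ((is.null(dispersion_coeffs) || is.null(fsr_ghz)) && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(dispersion_coeffs)) dispersion_coeffs <- meta$dispersion_coeffs
    if (is.null(fsr_ghz)) fsr_ghz <- meta$fsr_ghz
  }
  if (is.null(dispersion_coeffs) || is.null(fsr_ghz))
    stop("dispersion_coeffs and fsr_ghz required (no JSON sidecar found)")
  brillouin_spectrum(counts, dispersion_coeffs, fsr_ghz)
}

#' Write a cohort table to CSV at full numeric precision
#'
#' @param table Data.frame of per-cell records.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cohort table written by \code{\link{write_cohort_csv}}
#'
#' @param path CSV path.
#' @return Data.frame with numeric columns restored.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(x) || all(is.na(x) == is.na(df[[j]]))) {
      if (!all(is.na(x))) df[[j]] <- x
    }
  }
  df
}
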