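## Orchestration: per-cell processing of a paired hologram + spectrum,
## cohort aggregation, and the population statistics (Welch tests,
## normality checks, correlation fits).

#' Pipeline configuration
#'
#' Bundles the physical constants with the processing options of every
#' stage. Can be read from / written to YAML or JSON; every per-cell record
#' carries the resolved configuration as provenance.
#'
#' @param consts A \code{\link{physical_constants}}.
#' @param poly_order Background polynomial order.
#' @param crop_frac,taper_frac Demodulation crop window parameters (see
#'   \code{\link{demodulate}}).
#' @param radius_range_um Hough radius search range (um).
#' @param edge_threshold_frac Hough edge threshold fraction.
#' @param mass_domain Dry-mass integration domain: segmentation
#'   \code{"mask"} (default) or fitted \code{"disc"}.
#' @param mask_dilate_px Dilation radius (px) applied to the automated
#'   segmentation before it is used to exclude the cell from the background
#'   fit and to bound the dry-mass integral. Point-spread blur pushes cell
#'   phase beyond the thresholded component; the default (24 px, about four
#'   PSF sigmas at the default simulation settings) keeps that spread out
#'   of the background fit and inside the mass integral.
#' @param prominence_frac Peak-search prominence threshold fraction.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(consts = physical_constants(),
                            poly_order = 2,
                            crop_frac = 1 / 8,
                            taper_frac = 0.6,
                            radius_range_um = c(4, 10),
                            edge_threshold_frac = 0.25,
                            mass_domain = c("mask", "disc"),
                            mask_dilate_px = 24L,
                            prominence_frac = 0.02) {
  mass_domain <- match.arg(mass_domain)
  structure(list(consts = consts, poly_order = poly_order,
                 crop_frac = crop_frac, taper_frac = taper_frac,
                 radius_range_um = radius_range_um,
                 edge_threshold_frac = edge_threshold_frac,
                 mass_domain = mass_domain,
                 mask_dilate_px = as.integer(mask_dilate_px),
                 prominence_frac = prominence_frac),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path (.yaml/.yml or .json).
#' @return A \code{\link{pipeline_config}}.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  consts <- do.call(physical_constants, as.list(raw$consts %||% list()))
  opts <- raw[setdiff(names(raw), "consts")]
  do.call(pipeline_config, c(list(consts = consts), opts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hologram to background-corrected, segmented phase map
#'
#' The full QPI preprocessing: demodulation, unwrapping, a first-pass
#' background removal (no mask) to make segmentation robust, segmentation,
#' then the final background fit over the true background pixels. The
#' returned phase map carries the cell mask.
#'
#' @param interf An \code{\link{interferogram}} or TIFF path.
#' @param config A \code{\link{pipeline_config}}.
#' @param mask Optional externally supplied logical mask (or mask file
#'   path), reproducing a manual segmentation workflow.
#' @return A \code{\link{phase_map}} with mask.
#' @export
process_hologram <- function(interf, config = pipeline_config(), mask = NULL) {
  if (is.character(interf)) interf <- read_interferogram_tiff(interf)
  fld <- demodulate(interf, crop_frac = config$crop_frac,
                    taper_frac = config$taper_frac)
  uw <- unwrap(fld)
  uw$ground_truth <- interf$ground_truth
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.null(mask)) {
    rough <- remove_background(uw, poly_order = config$poly_order)
    mask <- segment_cell(rough)
    if (config$mask_dilate_px > 0) {
      brush <- EBImage::makeBrush(2 * config$mask_dilate_px + 1, "disc")
      mask <- as.matrix(EBImage::imageData(
        EBImage::dilate(EBImage::Image(mask * 1), brush))) > 0.5
    }
  }
  out <- remove_background(uw, mask = mask, poly_order = config$poly_order)
  out$mask <- mask
  out
}

## Disc mask from a sphere fit (used when mass_domain = "disc").
disc_mask <- function(fit, shape_px) {
  r_px <- fit$diameter_um / 2 / fit$pixel_um
  d2 <- outer((seq_len(shape_px[1]) - 1 - fit$center_px[1])^2,
              (seq_len(shape_px[2]) - 1 - fit$center_px[2])^2, "+")
  d2 <= r_px^2
}

#' Analyze one cell from a paired hologram and Brillouin spectrum
#'
#' Runs the full chain: demodulate, unwrap, segment, background-correct,
#' sphere fit, QPI parameters; Lorentzian spectrum fits, shift and
#' corrected linewidth; viscoelastic combination. Any stage error is
#' re-signalled with the stage name prefixed.
#'
#' @param hologram An \code{\link{interferogram}} or TIFF path.
#' @param spectrum A \code{\link{brillouin_spectrum}} or CSV/TIFF path.
#' @param config A \code{\link{pipeline_config}}.
#' @param mask Optional mask (matrix or file path) overriding automated
#'   segmentation.
#' @param condition Condition label recorded in the output.
#' @return One-row data.frame with the 15 biophysical parameters, SNR,
#'   sphere-fit metadata and provenance columns.
#' @export
analyze_cell <- function(hologram, spectrum, config = pipeline_config(),
                         mask = NULL, condition = NA_character_) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  holo_path <- if (is.character(hologram)) hologram else NA_character_
  spec_path <- if (is.character(spectrum)) spectrum else NA_character_
  phase <- stage("holography", process_hologram(hologram, config, mask))
  fit <- stage("geometry", fit_sphere(
    phase, radius_range_um = config$radius_range_um,
    calibration_factor = config$consts$hough_calibration,
    edge_threshold_frac = config$edge_threshold_frac))
  qpi <- stage("qpi_params", {
    m <- if (config$mass_domain == "disc")
      disc_mask(fit, dim(phase$phi)) else phase$mask
    cell_biophysics(phase, fit, mask = m, consts = config$consts)
  })
  br <- stage("brillouin", {
    if (is.character(spectrum)) spectrum <- read_spectrum(spectrum)
    analyze_spectrum(spectrum,
                     instrument_fwhm_ghz = config$consts$instrument_fwhm_ghz,
                     prominence_frac = config$prominence_frac)
  })
  ve <- stage("viscoelastic", viscoelastic_params(
    qpi$rho_g_per_ml, qpi$n_cell_mean, br$nu_b_ghz, br$gamma_b_ghz,
    lambda_b_nm = config$consts$lambda_b_nm))
  data.frame(condition = condition,
             diameter_um = qpi$diameter_um,
             n_cell_mean = qpi$n_cell_mean,
             m_dry_pg = qpi$m_dry_pg,
             v_fluid_um3 = qpi$v_fluid_um3,
             v_dry_um3 = qpi$v_dry_um3,
             v_cell_um3 = qpi$v_cell_um3,
             m_fluid_pg = qpi$m_fluid_pg,
             rho_g_per_ml = qpi$rho_g_per_ml,
             u_h2o_pct = qpi$u_h2o_pct,
             theta_h2o_pct = qpi$theta_h2o_pct,
             nu_b_ghz = br$nu_b_ghz,
             gamma_b_ghz = br$gamma_b_ghz,
             m_prime_gpa = ve$m_prime_gpa,
             m_dprime_gpa = ve$m_dprime_gpa,
             eta_pa_s = ve$eta_pa_s,
             loss_tangent = ve$loss_tangent,
             snr_db = br$snr_db,
             hough_score = fit$accumulator_score,
             hologram_path = holo_path,
             spectrum_path = spec_path,
             stringsAsFactors = FALSE)
}

#' Analyze a simulated cohort end to end
#'
#' Convenience wrapper running \code{\link{analyze_cell}} over the output
#' of \code{\link{make_cohort}}; failed cells are recorded with an error
#' column instead of aborting the cohort.
#'
#' @param cells List from \code{\link{make_cohort}}.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data.frame with one row per successfully processed cell plus an
#'   \code{error} column (NA on success).
#' @export
analyze_cohort <- function(cells, config = pipeline_config()) {
  rows <- lapply(cells, function(cl) {
    tryCatch({
      r <- analyze_cell(cl$interferogram, cl$spectrum, config,
                        condition = cl$condition)
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(condition = cl$condition, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    template <- rows[[which(vapply(rows, ncol, 1L) == max(vapply(rows, ncol, 1L)))[1]]]
    miss <- setdiff(names(template), names(r))
    for (m in miss) r[[m]] <- NA
    r[names(template)]
  }))
  out
}

## numeric parameter columns summarized / tested at cohort level
.PARAM_COLS <- c("diameter_um", "n_cell_mean", "m_dry_pg", "v_fluid_um3",
                 "v_dry_um3", "v_cell_um3", "rho_g_per_ml", "u_h2o_pct",
                 "theta_h2o_pct", "nu_b_ghz", "gamma_b_ghz", "m_prime_gpa",
                 "eta_pa_s", "m_dprime_gpa", "loss_tangent")

#' Per-condition summary: mean, SD and N for each parameter
#'
#' @param table Cohort data.frame (as from \code{\link{analyze_cohort}} or
#'   \code{\link{draw_cohort_params}}).
#' @param params Parameter columns to summarize; defaults to the standard
#'   15 present in the table.
#' @return Data.frame with columns condition, parameter, mean, sd, n.
#' @export
summarize_cohort <- function(table, params = NULL) {
  if (is.null(params)) params <- intersect(.PARAM_COLS, names(table))
  if (nrow(table) == 0 || length(params) == 0)
    return(data.frame(condition = character(0), parameter = character(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0)))
  conds <- unique(table$condition)
  do.call(rbind, lapply(conds, function(cd) {
    sub <- table[table$condition == cd, , drop = FALSE]
    do.call(rbind, lapply(params, function(p) {
      x <- sub[[p]][!is.na(sub[[p]])]
      data.frame(condition = cd, parameter = p,
                 mean = mean(x), sd = stats::sd(x), n = length(x),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Compare two conditions parameter by parameter
#'
#' Welch's two-sample t-test (two-tailed, unequal variance,
#' Welch-Satterthwaite degrees of freedom) per parameter, plus a
#' Kolmogorov-Smirnov normality check per group (against a normal with the
#' group's sample moments).
#'
#' @param table Cohort data.frame.
#' @param condition_a,condition_b Condition labels to compare.
#' @param params Parameter columns; defaults to the standard set present.
#' @return Data.frame with means, SDs, t statistic, df, p value and the
#'   per-group KS normality p values.
#' @export
compare_groups <- function(table, condition_a, condition_b, params = NULL) {
  if (is.null(params)) params <- intersect(.PARAM_COLS, names(table))
  a <- table[table$condition == condition_a, , drop = FALSE]
  b <- table[table$condition == condition_b, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 cells per condition")
  do.call(rbind, lapply(params, function(p) {
    xa <- a[[p]][!is.na(a[[p]])]; xb <- b[[p]][!is.na(b[[p]])]
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    ksp <- function(x) {
      if (stats::sd(x) == 0) return(NA_real_)
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
    data.frame(parameter = p,
               mean_a = mean(xa), sd_a = stats::sd(xa), n_a = length(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb), n_b = length(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               ks_normality_p_a = ksp(xa), ks_normality_p_b = ksp(xb),
               stringsAsFactors = FALSE)
  }))
}

#' Linear correlation between two parameters
#'
#' Ordinary least-squares fit of \code{param_y} on \code{param_x}, per
#' condition and pooled, with R^2 and a 95 percent confidence band of the
#' fitted line evaluated on a grid.
#'
#' @param table Cohort data.frame.
#' @param param_x,param_y Column names.
#' @param by_condition Also fit each condition separately (default TRUE).
#' @param band_points Number of grid points for the confidence band.
#' @return Object of class \code{correlation_result}: data.frame
#'   \code{fits} (group, slope, intercept, r_squared, n) and list
#'   \code{bands} of per-group data.frames (x, fit, lwr, upr).
#' @export
correlate <- function(table, param_x, param_y, by_condition = TRUE,
                      band_points = 50) {
  groups <- list(pooled = table)
  if (by_condition)
    for (cd in unique(table$condition))
      groups[[cd]] <- table[table$condition == cd, , drop = FALSE]
  fits <- list(); bands <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    x <- sub[[param_x]]; y <- sub[[param_y]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop(sprintf("need >= 3 points per fit (group %s)", g))
    if (stats::sd(x) == 0) stop(sprintf("degenerate x (zero variance) in group %s", g))
    fit <- stats::lm(y ~ x)
    grid <- data.frame(x = seq(min(x), max(x), length.out = band_points))
    ci <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
    fits[[g]] <- data.frame(group = g,
                            slope = unname(stats::coef(fit)[2]),
                            intercept = unname(stats::coef(fit)[1]),
                            r_squared = summary(fit)$r.squared,
                            n = length(x), stringsAsFactors = FALSE)
    bands[[g]] <- data.frame(x = grid$x, fit = ci[, "fit"],
                             lwr = ci[, "lwr"], upr = ci[, "upr"])
  }
  structure(list(param_x = param_x, param_y = param_y,
                 fits = do.call(rbind, fits), bands = bands),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Correlation %s ~ %s\n", x$param_y, x$param_x))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Violin plot of one parameter across conditions
#'
#' Convenience visualization mirroring the usual presentation of cohort
#' data; requires ggplot2.
#'
#' @param table Cohort data.frame.
#' @param param Parameter column to plot.
#' @return A ggplot object.
#' @export
plot_cohort <- function(table, param = "nu_b_ghz") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(condition = table$condition, value = table[[param]])
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = value,
                                   fill = condition)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.08, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = param)
}
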