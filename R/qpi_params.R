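## Phase map + sphere fit -> the nine QPI-derived biophysical parameters:
## refractive index, dry mass, and the two-component mixture model yielding
## volumes, fluid mass, density and water content.

#' Refractive-index contrast map
#'
#' Delta n(x, y) = (lambda_Q / 2 pi) * phi(x, y) / h(x, y) inside the fitted
#' disc; NA outside (or wherever h = 0).
#'
#' @param phase A \code{\link{phase_map}} (background-corrected).
#' @param thick A \code{\link{thickness_map}} on the same grid.
#' @return Numeric matrix of RI contrast, NA where undefined.
#' @export
ri_map <- function(phase, thick) {
  stopifnot(inherits(phase, "phase_map"), inherits(thick, "thickness_map"),
            identical(dim(phase$phi), dim(thick$h)))
  lambda_um <- phase$lambda_q_nm * .NM_TO_UM
  dn <- matrix(NA_real_, nrow(phase$phi), ncol(phase$phi))
  ok <- thick$h > 0
  dn[ok] <- lambda_um / (2 * pi) * phase$phi[ok] / thick$h[ok]
  dn
}

#' Mean cellular refractive index
#'
#' Averages the RI contrast over pixels with r <= 0.9 R from the fitted
#' centre — a band of width R/10 inside the boundary is excluded to avoid
#' edge effects — then adds the medium index.
#'
#' @param dn RI-contrast matrix from \code{\link{ri_map}}.
#' @param fit A \code{\link{sphere_fit}}.
#' @param consts A \code{\link{physical_constants}} (supplies
#'   \code{n_medium}).
#' @param exclusion_frac Fraction of the radius excluded at the boundary
#'   (default 0.1).
#' @return Mean cell refractive index (scalar).
#' @export
mean_ri <- function(dn, fit, consts = physical_constants(),
                    exclusion_frac = 0.1) {
  stopifnot(inherits(fit, "sphere_fit"), is.matrix(dn))
  nr <- nrow(dn); nc <- ncol(dn)
  r_um <- sqrt(outer(((seq_len(nr) - 1 - fit$center_px[1]) * fit$pixel_um)^2,
                     ((seq_len(nc) - 1 - fit$center_px[2]) * fit$pixel_um)^2,
                     "+"))
  keep <- r_um <= (1 - exclusion_frac) * fit$diameter_um / 2 & !is.na(dn)
  if (!any(keep)) stop("no valid interior pixels after edge exclusion")
  mean(dn[keep]) + consts$n_medium
}

#' Cellular dry mass from the integrated phase
#'
#' m_dry = (lambda_Q / (2 pi alpha)) * sum(phi) * pixel_area, in picograms
#' (lambda in um, alpha in um^3/pg — numerically equal to mL/g — and pixel
#' area in um^2). A negative total phase triggers a warning (noise-dominated
#' image) but the value is still returned.
#'
#' @param phase A \code{\link{phase_map}} (background-corrected).
#' @param mask Logical matrix restricting the integration domain; defaults
#'   to the phase map's mask, or the whole frame if none.
#' @param consts A \code{\link{physical_constants}}.
#' @return Dry mass in pg.
#' @export
dry_mass <- function(phase, mask = NULL, consts = physical_constants()) {
  stopifnot(inherits(phase, "phase_map"))
  if (is.null(mask)) mask <- phase$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase$phi), ncol(phase$phi))
  lambda_um <- phase$lambda_q_nm * .NM_TO_UM
  total_phi <- sum(phase$phi[mask])
  if (total_phi < 0) warning("negative integrated phase: noise-dominated image")
  lambda_um / (2 * pi * consts$alpha_ml_per_g) * total_phi * phase$pixel_um^2
}

#' Two-component mixture model of the cell
#'
#' Decomposes the cell into dry (protein-like) and fluid (water-like)
#' compartments: V_cell = (4/3) pi (D/2)^3, V_dry = m_dry / rho_dry,
#' V_fluid = V_cell - V_dry, m_fluid = rho_fluid V_fluid, density
#' rho = (m_dry + m_fluid) / V_cell, and the water fractions by volume
#' (theta = V_fluid / V_cell) and by mass (u = m_fluid / (m_fluid + m_dry)),
#' both as percentages.
#'
#' @param diameter_um Calibrated cell diameter (um).
#' @param m_dry_pg Dry mass (pg).
#' @param consts A \code{\link{physical_constants}}.
#' @return Named list: \code{v_cell_um3}, \code{v_dry_um3},
#'   \code{v_fluid_um3}, \code{m_fluid_pg}, \code{rho_g_per_ml},
#'   \code{u_h2o_pct}, \code{theta_h2o_pct}.
#' @examples
#' mixture_model(13.1, 225)  # control-like cell
#' @export
mixture_model <- function(diameter_um, m_dry_pg,
                          consts = physical_constants()) {
  stopifnot(diameter_um > 0, m_dry_pg >= 0)
  v_cell <- 4 / 3 * pi * (diameter_um / 2)^3
  v_dry <- m_dry_pg / consts$rho_dry
  if (v_dry > v_cell) stop("dry volume exceeds cell volume")
  v_fluid <- v_cell - v_dry
  m_fluid <- consts$rho_fluid * v_fluid
  rho <- (m_dry_pg + m_fluid) / v_cell
  list(v_cell_um3 = v_cell, v_dry_um3 = v_dry, v_fluid_um3 = v_fluid,
       m_fluid_pg = m_fluid, rho_g_per_ml = rho,
       u_h2o_pct = 100 * m_fluid / (m_fluid + m_dry_pg),
       theta_h2o_pct = 100 * v_fluid / v_cell)
}

#' Assemble the QPI-derived per-cell record
#'
#' Runs \code{\link{ri_map}}, \code{\link{mean_ri}}, \code{\link{dry_mass}}
#' and \code{\link{mixture_model}} on a background-corrected phase map and
#' sphere fit.
#'
#' @param phase A \code{\link{phase_map}}.
#' @param fit A \code{\link{sphere_fit}}.
#' @param mask Logical matrix: dry-mass integration domain (defaults to the
#'   phase map's mask).
#' @param consts A \code{\link{physical_constants}}.
#' @return Object of class \code{cell_biophysics}: named list of the nine
#'   QPI parameters (diameter, cell/dry/fluid volume, mean RI, dry and
#'   fluid mass, density, water content by mass and volume).
#' @export
cell_biophysics <- function(phase, fit, mask = NULL,
                            consts = physical_constants()) {
  thick <- thickness_map(fit, phase = phase)
  dn <- ri_map(phase, thick)
  n_mean <- mean_ri(dn, fit, consts)
  m_dry <- dry_mass(phase, mask, consts)
  mix <- mixture_model(fit$diameter_um, m_dry, consts)
  structure(c(list(diameter_um = fit$diameter_um, n_cell_mean = n_mean,
                   m_dry_pg = m_dry), mix),
            class = "cell_biophysics")
}

#' @export
print.cell_biophysics <- function(x, ...) {
  cat(sprintf(paste0(
    "CellBiophysics: D %.2f um, V %.0f um^3, n %.4f, m_dry %.1f pg,\n",
    "  rho %.4f g/mL, water %.1f%% (mass) / %.1f%% (volume)\n"),
    x$diameter_um, x$v_cell_um3, x$n_cell_mean, x$m_dry_pg,
    x$rho_g_per_ml, x$u_h2o_pct, x$theta_h2o_pct))
  invisible(x)
}
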