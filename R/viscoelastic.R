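## Combine QPI-derived density and refractive index with the Brillouin
## shift and linewidth into the longitudinal viscoelastic parameters.
## Unit handbook (centralized in constants.R): g/mL -> kg/m^3 (x1000),
## GHz -> Hz (x1e9), nm -> m (x1e-9), Pa -> GPa (x1e-9).

#' Longitudinal (storage) modulus from the Brillouin shift
#'
#' M' = rho (nu_B lambda_B / (2 n))^2, the real part of the complex
#' longitudinal modulus probed at GHz frequencies.
#'
#' @param rho_g_per_ml Mass density (g/mL).
#' @param nu_b_ghz Brillouin shift (GHz).
#' @param n_cell Refractive index at the Brillouin wavelength.
#' @param lambda_b_nm Brillouin excitation wavelength (nm).
#' @return M' in GPa.
#' @examples
#' longitudinal_modulus(1.053, 7.865, 1.371)  # ~2.452 GPa
#' @export
longitudinal_modulus <- function(rho_g_per_ml, nu_b_ghz, n_cell,
                                 lambda_b_nm = 532) {
  stopifnot(rho_g_per_ml > 0, nu_b_ghz >= 0, n_cell > 0, lambda_b_nm > 0)
  v <- nu_b_ghz * .GHZ_TO_HZ * lambda_b_nm * .NM_TO_M / (2 * n_cell)  # m/s
  rho_g_per_ml * .G_PER_ML_TO_KG_M3 * v^2 * .PA_TO_GPA
}

#' Loss modulus from the Brillouin linewidth
#'
#' M'' = rho Gamma_B nu_B (lambda_B / (2 n))^2, the imaginary (dissipative)
#' part of the complex longitudinal modulus.
#'
#' @param rho_g_per_ml Mass density (g/mL).
#' @param gamma_b_ghz Instrument-corrected Brillouin linewidth (GHz).
#' @param nu_b_ghz Brillouin shift (GHz).
#' @param n_cell Refractive index at the Brillouin wavelength.
#' @param lambda_b_nm Brillouin excitation wavelength (nm).
#' @return M'' in GPa.
#' @export
loss_modulus <- function(rho_g_per_ml, gamma_b_ghz, nu_b_ghz, n_cell,
                         lambda_b_nm = 532) {
  stopifnot(rho_g_per_ml > 0, gamma_b_ghz >= 0, nu_b_ghz >= 0, n_cell > 0,
            lambda_b_nm > 0)
  rho_g_per_ml * .G_PER_ML_TO_KG_M3 *
    (gamma_b_ghz * .GHZ_TO_HZ) * (nu_b_ghz * .GHZ_TO_HZ) *
    (lambda_b_nm * .NM_TO_M / (2 * n_cell))^2 * .PA_TO_GPA
}

#' Longitudinal viscosity
#'
#' eta = M'' / (2 pi nu_B), in pascal-seconds.
#'
#' @param m_dprime_gpa Loss modulus (GPa).
#' @param nu_b_ghz Brillouin shift (GHz), > 0.
#' @return eta in Pa s.
#' @export
longitudinal_viscosity <- function(m_dprime_gpa, nu_b_ghz) {
  if (nu_b_ghz <= 0) stop("nu_b_ghz must be > 0")
  (m_dprime_gpa / .PA_TO_GPA) / (2 * pi * nu_b_ghz * .GHZ_TO_HZ)
}

#' Loss tangent
#'
#' tan(phi) = M'' / M', the relative weight of viscous to elastic response.
#'
#' @param m_prime_gpa Storage modulus (GPa), > 0.
#' @param m_dprime_gpa Loss modulus (GPa).
#' @return Dimensionless loss tangent.
#' @export
loss_tangent <- function(m_prime_gpa, m_dprime_gpa) {
  if (m_prime_gpa <= 0) stop("m_prime_gpa must be > 0")
  m_dprime_gpa / m_prime_gpa
}

#' All four viscoelastic parameters for one cell
#'
#' Evaluates M', M'', eta and tan(phi) from density, refractive index and
#' the Brillouin observables; the identities tan(phi) M' = M'' and
#' 2 pi nu_B eta = M'' hold exactly by construction. The complex modulus is
#' reported as the pair (M', M'').
#'
#' @param rho_g_per_ml Mass density (g/mL).
#' @param n_cell Mean cell refractive index.
#' @param nu_b_ghz Brillouin shift (GHz).
#' @param gamma_b_ghz Corrected Brillouin linewidth (GHz).
#' @param lambda_b_nm Brillouin wavelength (nm).
#' @return Object of class \code{viscoelastic_result}: \code{m_prime_gpa},
#'   \code{m_dprime_gpa}, \code{eta_pa_s}, \code{loss_tangent}.
#' @examples
#' viscoelastic_params(1.053, 1.371, 7.865, 1.279)
#' @export
viscoelastic_params <- function(rho_g_per_ml, n_cell, nu_b_ghz, gamma_b_ghz,
                                lambda_b_nm = 532) {
  mp <- longitudinal_modulus(rho_g_per_ml, nu_b_ghz, n_cell, lambda_b_nm)
  mpp <- loss_modulus(rho_g_per_ml, gamma_b_ghz, nu_b_ghz, n_cell, lambda_b_nm)
  structure(list(m_prime_gpa = mp, m_dprime_gpa = mpp,
                 eta_pa_s = longitudinal_viscosity(mpp, nu_b_ghz),
                 loss_tangent = loss_tangent(mp, mpp)),
            class = "viscoelastic_result")
}

#' @export
print.viscoelastic_result <- function(x, ...) {
  cat(sprintf(
    "Viscoelastic: M' %.3f GPa, M'' %.3f GPa, eta %.4f Pa s, tan(phi) %.3f\n",
    x$m_prime_gpa, x$m_dprime_gpa, x$eta_pa_s, x$loss_tangent))
  invisible(x)
}
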