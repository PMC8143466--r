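#' Hydrodynamic diameter from the diffusion coefficient
#'
#' Stokes-Einstein relation `DH = kB * T / (3 * pi * eta * D)`.
#'
#' @param D_m2s Translational diffusion coefficient in m^2/s (> 0).
#' @param temperature_K Temperature in kelvin.
#' @param eta_Pas Solvent viscosity in Pa s; default 8.9e-4 (water, 25 C).
#' @return Hydrodynamic diameter in m.
#' @export
hydrodynamic_diameter <- function(D_m2s, temperature_K = 298.15,
                                  eta_Pas = 8.9e-4) {
  if (any(D_m2s <= 0) || eta_Pas <= 0) stop("D and eta must be > 0")
  .kc$kB * temperature_K / (3 * pi * eta_Pas * D_m2s)
}

#' Zeta potential from electrophoretic mobility (Henry's relation)
#'
#' `zeta = 3 * mu * eta_w / (2 * eps_r * eps0 * f_kR)`.  With
#' `f_kR = 1.5` (Smoluchowski limit, appropriate for ~100 nm vesicles in
#' 150 mM salt) this reduces to `zeta = mu * eta_w / (eps_r * eps0)`.
#'
#' @param mu_m2Vs Electrophoretic mobility in m^2/(V s).
#' @param eta_Pas Water viscosity in Pa s; default 8.9e-4.
#' @param eps_r Relative permittivity; default 78.5.
#' @param f_kR Henry function value (> 0); default 1.5 (Smoluchowski).
#' @return Zeta potential in volts (linear in `mu_m2Vs`).
#' @export
zeta_from_mobility <- function(mu_m2Vs, eta_Pas = 8.9e-4, eps_r = 78.5,
                               f_kR = 1.5) {
  if (f_kR <= 0) stop("f_kR must be > 0")
  3 * mu_m2Vs * eta_Pas / (2 * eps_r * .kc$eps0 * f_kR)
}

#' Map the surface potential to the zeta potential at the shear plane
#'
#' Planar Poisson-Boltzmann decay of the diffuse-layer potential:
#' `tanh(zeta~/4) = tanh(psi~/4) * exp(-kappa * x)` with reduced potentials
#' `psi~ = e*psi/(kB*T)` and `x` the shear-plane distance from the surface.
#' At `x = 0` the identity is recovered; otherwise `|zeta| < |psi|` with the
#' same sign.
#'
#' @param psi_V Surface potential in volts (`|psi| < 0.4` V).
#' @param kappa_per_m Inverse Debye length in 1/m (see [debye_kappa()]).
#' @param x_m Shear-plane distance in m (>= 0).
#' @param temperature_K Temperature in kelvin.
#' @return Zeta potential in volts.
#' @examples
#' sol <- solution_conditions(7)
#' 1e3 * zeta_from_surface(-0.047, debye_kappa(sol), 3.7e-10)  # about -28 mV
#' @export
zeta_from_surface <- function(psi_V, kappa_per_m, x_m,
                              temperature_K = 298.15) {
  if (any(abs(psi_V) >= 0.4)) stop("|psi_V| must be < 0.4 V")
  if (any(x_m < 0)) stop("x_m must be >= 0")
  vt <- .kc$kB * temperature_K / .kc$e
  4 * vt * atanh(tanh(psi_V / (4 * vt)) * exp(-kappa_per_m * x_m))
}

#' Invert the diffuse-layer decay: surface potential from zeta
#'
#' Exact inverse of [zeta_from_surface()]:
#' `psi = (4 kB T / e) * atanh(tanh(e*zeta/(4 kB T)) * exp(+kappa * x))`.
#' Fails with a domain error when the amplified tanh argument leaves
#' `(-1, 1)` (zeta too large for the given `kappa * x`).
#'
#' @param zeta_V Zeta potential in volts.
#' @inheritParams zeta_from_surface
#' @return Surface potential in volts.
#' @export
surface_from_zeta <- function(zeta_V, kappa_per_m, x_m,
                              temperature_K = 298.15) {
  if (any(x_m < 0)) stop("x_m must be >= 0")
  vt <- .kc$kB * temperature_K / .kc$e
  arg <- tanh(zeta_V / (4 * vt)) * exp(kappa_per_m * x_m)
  if (any(abs(arg) >= 1))
    stop("inversion out of domain: |tanh| argument >= 1 ",
         "(zeta too large for this kappa*x)")
  4 * vt * atanh(arg)
}

#' Estimate the shear-plane distance from paired zeta/surface potentials
#'
#' From the diffuse-layer decay, `ln[tanh(zeta~/4)/tanh(psi~/4)] = -kappa*x`,
#' so a regression of the log tanh-ratio on `kappa`, forced through the
#' origin (at `kappa -> 0` the ratio is 1), has slope `-x`.  Requires pairs
#' at two or more ionic strengths.
#'
#' @param zeta_V Zeta potentials in volts.
#' @param psi_V Surface potentials in volts (same signs as `zeta_V`).
#' @param kappa_per_m Inverse Debye lengths in 1/m.
#' @param temperature_K Temperature in kelvin.
#' @return List of class `shear_plane`: `x_m`, `x_sd_m`, per-point
#'   `log_ratio`, `kappa_per_m`.
#' @export
estimate_shear_plane <- function(zeta_V, psi_V, kappa_per_m,
                                 temperature_K = 298.15) {
  n <- length(zeta_V)
  if (n < 2L || length(psi_V) != n || length(kappa_per_m) != n)
    stop("need matched zeta/psi/kappa vectors at >= 2 ionic strengths")
  if (any(sign(zeta_V) != sign(psi_V)))
    stop("zeta and surface potentials must have consistent signs")
  vt <- .kc$kB * temperature_K / .kc$e
  lr <- log(tanh(zeta_V / (4 * vt)) / tanh(psi_V / (4 * vt)))
  fit <- stats::lm(lr ~ 0 + kappa_per_m)
  x <- -unname(stats::coef(fit)[1])
  x_sd <- if (n > 1L)
    unname(suppressWarnings(summary(fit))$coefficients[1, 2]) else NA_real_
  structure(list(x_m = x, x_sd_m = x_sd, log_ratio = lr,
                 kappa_per_m = kappa_per_m), class = "shear_plane")
}

#' @export
print.shear_plane <- function(x, ...) {
  cat(sprintf("shear plane x = %.2f A (sd %.2g A, %d ionic strengths)\n",
              1e10 * x$x_m, 1e10 * x$x_sd_m, length(x$kappa_per_m)))
  invisible(x)
}
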