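#' Inverse Debye screening length
#'
#' Computes the inverse Debye length `kappa` of a symmetric 1:1 electrolyte,
#' `kappa^2 = 2e3 * N_A * e^2 * c_salt / (eps0 * eps_r * kB * T)`.
#' For 150 mM salt in water at 25 C the Debye length `1/kappa` is about
#' 7.9 angstrom.
#'
#' @param solution A [solution_conditions()] object.
#' @return Inverse Debye length in 1/m.
#' @examples
#' 1e10 / debye_kappa(solution_conditions(7))  # Debye length in angstrom
#' @export
debye_kappa <- function(solution) {
  stopifnot(inherits(solution, "solution_conditions"))
  with(.kc, sqrt(2e3 * N_A * e^2 * solution$c_salt_M /
                   (eps0 * solution$eps_r * kB * solution$temperature_K)))
}

#' Grahame equation: diffuse-layer charge density at a planar surface
#'
#' Charge density carried by the diffuse ionic atmosphere balancing a planar
#' surface at potential `psi` in a 1:1 electrolyte:
#' `sigma = sqrt(8000 * eps0 * eps_r * R * T * c_salt) * sinh(e*psi / (2*kB*T))`.
#'
#' The sinh argument uses the standard Grahame factor `e*psi/(2*kB*T)`; with
#' the membrane defaults of this package it places the bare 7POPC:3POPG
#' surface at about -47 mV.
#'
#' @param psi_V Surface potential in volts (sanity bound `|psi| < 0.5` V).
#' @param solution A [solution_conditions()] object.
#' @return Surface charge density in C/m^2 (same sign as `psi_V`).
#' @seealso [grahame_sigma_linear()] for the Debye-Hueckel linearization.
#' @export
grahame_sigma <- function(psi_V, solution) {
  stopifnot(inherits(solution, "solution_conditions"))
  if (any(abs(psi_V) >= 0.5)) stop("|psi_V| must be < 0.5 V")
  pref <- with(.kc, sqrt(8000 * eps0 * solution$eps_r * R *
                           solution$temperature_K * solution$c_salt_M))
  pref * sinh(.kc$e * psi_V / (2 * .kc$kB * solution$temperature_K))
}

#' Debye-Hueckel linearization of the Grahame equation
#'
#' `sigma = eps0 * eps_r * kappa * psi`, valid for `|psi| << kB*T/e`.
#'
#' @inheritParams grahame_sigma
#' @return Surface charge density in C/m^2.
#' @export
grahame_sigma_linear <- function(psi_V, solution) {
  stopifnot(inherits(solution, "solution_conditions"))
  .kc$eps0 * solution$eps_r * debye_kappa(solution) * psi_V
}

#' Lipid-side surface charge density with bound sodium and adsorbed peptide
#'
#' `sigma = (e / AL) * (-XA + XNa + Xb * zp)` where `XNa = KNa * CNa` is the
#' fraction of head groups with a bound sodium ion (evaluated at the bulk
#' sodium concentration), `Xb` the adsorbed peptide per outer-leaflet lipid
#' and `zp` the peptide net charge.
#'
#' @param membrane A [membrane_spec()] object.
#' @param solution A [solution_conditions()] object (supplies `CNa`).
#' @param Xb Adsorbed peptide per outer-leaflet lipid (>= 0).
#' @param zp Peptide net charge in elementary charges.
#' @return Surface charge density in C/m^2.
#' @export
lipid_sigma <- function(membrane, solution, Xb = 0, zp = 0) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(solution, "solution_conditions"))
  if (any(Xb < 0)) stop("Xb must be >= 0")
  XNa <- membrane$KNa_per_M * solution$c_salt_M
  AL_m2 <- membrane$AL_A2 * 1e-20
  (.kc$e / AL_m2) * (-membrane$XA + XNa + Xb * zp)
}

#' Solve for the membrane surface potential
#'
#' Finds the potential `psi` at which the lipid-side charge density
#' ([lipid_sigma()]) equals the diffuse-layer charge density
#' ([grahame_sigma()]).  Because the lipid-side density does not depend on
#' `psi`, the monotone Grahame relation can be inverted in closed form,
#' `psi = (2 kB T / e) * asinh(sigma / prefactor)`, which is exact to
#' machine precision; the root is unique.  An error is raised if the
#' solution falls outside the physical bracket.
#'
#' @inheritParams lipid_sigma
#' @param bracket_V Admissible potential range in volts.
#' @return Surface potential in volts.
#' @examples
#' # bare 7POPC:3POPG membrane in 150 mM salt: about -47 mV
#' 1e3 * solve_surface_potential(membrane_spec(), solution_conditions(5.5))
#' @export
solve_surface_potential <- function(membrane, solution, Xb = 0, zp = 0,
                                    bracket_V = c(-0.3, 0.3)) {
  sigma <- lipid_sigma(membrane, solution, Xb, zp)
  if (!is.finite(sigma)) stop("lipid surface charge density is not finite")
  pref <- with(.kc, sqrt(8000 * eps0 * solution$eps_r * R *
                           solution$temperature_K * solution$c_salt_M))
  psi <- 2 * .kc$kB * solution$temperature_K / .kc$e * asinh(sigma / pref)
  if (psi < bracket_V[1] || psi > bracket_V[2])
    stop("surface potential outside [", 1e3 * bracket_V[1], ", ",
         1e3 * bracket_V[2], "] mV")
  psi
}

#' Surface pH from the bulk pH and the surface potential
#'
#' Protons follow a Boltzmann distribution in the double layer, so the pH at
#' the membrane surface is shifted from the bulk by
#' `pHs = pHb + F * psi / (ln(10) * R * T)`.  A negative surface potential
#' makes the interface more acidic (e.g. bulk 5.5 maps to about 4.7 at
#' -47 mV).
#'
#' @param pH_bulk Bulk pH.
#' @param psi_V Surface potential in volts.
#' @param temperature_K Temperature in kelvin.
#' @return Surface pH (dimensionless).
#' @export
surface_pH <- function(pH_bulk, psi_V, temperature_K = 298.15) {
  pH_bulk + .kc$F * psi_V / (log(10) * .kc$R * temperature_K)
}

#' Peptide concentration at the membrane surface (Boltzmann enrichment)
#'
#' `CM = Cf * exp(-zp * e * psi / (kB * T))`: a cationic peptide is enriched
#' at a negatively charged surface relative to its free bulk concentration.
#'
#' @param Cf_M Free peptide concentration in mol/L (>= 0).
#' @param zp Peptide net charge in elementary charges.
#' @param psi_V Surface potential in volts.
#' @param temperature_K Temperature in kelvin.
#' @return Near-membrane concentration in mol/L.
#' @export
boltzmann_surface_conc <- function(Cf_M, zp, psi_V, temperature_K = 298.15) {
  if (any(Cf_M < 0)) stop("Cf_M must be >= 0")
  Cf_M * exp(-zp * .kc$e * psi_V / (.kc$kB * temperature_K))
}
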