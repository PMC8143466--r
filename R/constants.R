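# CODATA 2018 values, SI units.  All electrostatic formulas read from this
# single table so unit plumbing is testable in one place.
.kc <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  N_A  = 6.02214076e23,     # Avogadro number, 1/mol
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  F    = 96485.33212,       # Faraday constant, C/mol
  R    = 8.314462618        # molar gas constant, J/(mol K)
)

#' Physical constants used throughout the package
#'
#' Returns the frozen table of CODATA physical constants (SI units) that every
#' electrostatic formula in the package reads from: elementary charge `e` (C),
#' Boltzmann constant `kB` (J/K), Avogadro number `N_A` (1/mol), vacuum
#' permittivity `eps0` (F/m), Faraday constant `F` (C/mol) and molar gas
#' constant `R` (J/(mol K)).
#'
#' @return A named list of numeric constants.
#' @examples
#' phys_constants()$F / phys_constants()$R  # F/R in K/V
#' @export
phys_constants <- function() .kc

# thermal voltage kB*T/e = R*T/F, volts
.thermal_voltage <- function(temperature_K) .kc$R * temperature_K / .kc$F
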