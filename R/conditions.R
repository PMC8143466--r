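#' Bulk solution conditions
#'
#' Container for the bulk aqueous phase that every electrostatic formula reads
#' from: bulk pH, absolute temperature, monovalent salt concentration and the
#' relative permittivity of the medium.
#'
#' @param pH_bulk Bulk solution pH, in `[0, 14]`.
#' @param c_salt_M Monovalent (1:1) salt concentration in mol/L; default 0.15
#'   (150 mM NaCl, the buffer used for the vesicle experiments).
#' @param temperature_K Absolute temperature in kelvin; default 298.15 (25 C).
#' @param eps_r Relative permittivity of the medium; default 78.5 (water).
#' @return An object of class `solution_conditions`.
#' @examples
#' solution_conditions(pH_bulk = 5.5)
#' @export
solution_conditions <- function(pH_bulk, c_salt_M = 0.15,
                                temperature_K = 298.15, eps_r = 78.5) {
  stopifnot(is.numeric(pH_bulk), length(pH_bulk) == 1L)
  if (pH_bulk < 0 || pH_bulk > 14) stop("pH_bulk must be in [0, 14]")
  if (!is.numeric(c_salt_M) || c_salt_M <= 0) stop("c_salt_M must be > 0")
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0")
  if (!is.numeric(eps_r) || eps_r <= 0) stop("eps_r must be > 0")
  structure(list(pH_bulk = pH_bulk, c_salt_M = c_salt_M,
                 temperature_K = temperature_K, eps_r = eps_r),
            class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("solution: pH %.2f, %.0f mM 1:1 salt, %.2f K, eps_r %.1f\n",
              x$pH_bulk, 1e3 * x$c_salt_M, x$temperature_K, x$eps_r))
  invisible(x)
}

#' Membrane composition and bare surface charge parameters
#'
#' Describes the planar lipid surface: anionic lipid mole fraction `XA`, area
#' per lipid `AL` and the intrinsic sodium binding constant `KNa` of the lipid
#' head groups.  Together with the solution these define the bare surface
#' charge density `(e/AL) * (-XA + KNa*CNa)`.
#'
#' @param XA Anionic lipid fraction, in `[0, 1]`; default 0.3 (7POPC:3POPG).
#' @param AL_A2 Area per lipid in square angstrom; default 70.
#' @param KNa_per_M Intrinsic sodium binding constant in 1/M; default 0.6.
#' @return An object of class `membrane_spec`.
#' @examples
#' membrane_spec()  # the 7POPC:3POPG default
#' @export
membrane_spec <- function(XA = 0.3, AL_A2 = 70, KNa_per_M = 0.6) {
  if (!is.numeric(XA) || XA < 0 || XA > 1) stop("XA must be in [0, 1]")
  if (!is.numeric(AL_A2) || AL_A2 <= 0) stop("AL_A2 must be > 0")
  if (!is.numeric(KNa_per_M) || KNa_per_M < 0) stop("KNa_per_M must be >= 0")
  structure(list(XA = XA, AL_A2 = AL_A2, KNa_per_M = KNa_per_M),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("membrane: XA %.2f, AL %.1f A^2, KNa %.2f 1/M\n",
              x$XA, x$AL_A2, x$KNa_per_M))
  invisible(x)
}
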