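#' Titratable site of a peptide
#'
#' @param name Site label (e.g. `"Asp"`, `"Lys"`, `"Nterm"`).
#' @param kind `"acid"` (charged when deprotonated) or `"base"` (charged when
#'   protonated).
#' @param count Number of equivalent sites of this kind (>= 1).
#' @param pKa_ref Reference (intrinsic) pKa, in (0, 14).
#' @param fixed_protonated If `TRUE`, the site is pinned fully protonated
#'   (f = 1) regardless of pH and potential, mirroring simulations that hold
#'   the N-terminus protonated.
#' @return An object of class `ionizable_site`.
#' @export
ionizable_site <- function(name, kind = c("acid", "base"), count = 1L,
                           pKa_ref, fixed_protonated = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(count) || count < 1) stop("count must be >= 1")
  if (!is.numeric(pKa_ref) || pKa_ref <= 0 || pKa_ref >= 14)
    stop("pKa_ref must be in (0, 14)")
  structure(list(name = name, kind = kind, count = as.integer(count),
                 pKa_ref = pKa_ref, fixed_protonated = isTRUE(fixed_protonated)),
            class = "ionizable_site")
}

#' Peptide ionization model
#'
#' A named collection of [ionizable_site()]s defining the pH- and
#' potential-dependent net charge of a peptide.
#'
#' @param name Peptide label.
#' @param sites A list of [ionizable_site()] objects (at least one).
#' @return An object of class `peptide_model`.
#' @seealso [peptide_preset()] for the built-in MP1 and H-MP1 models.
#' @export
peptide_model <- function(name, sites) {
  if (length(sites) < 1L || !all(vapply(sites, inherits, TRUE, "ionizable_site")))
    stop("sites must be a non-empty list of ionizable_site objects")
  structure(list(name = name, sites = sites), class = "peptide_model")
}

#' @export
print.peptide_model <- function(x, ...) {
  cat("peptide:", x$name, "\n")
  for (s in x$sites)
    cat(sprintf("  %-6s %s x%d  pKa %.1f%s\n", s$name, s$kind, s$count,
                s$pKa_ref, if (s$fixed_protonated) " (pinned protonated)" else ""))
  invisible(x)
}

#' Built-in peptide ionization presets
#'
#' `"MP1"` (IDWKKLLDAAKQIL-NH2): 2 Asp (pKa 4.0), 3 Lys (10.4), N-terminus
#' (8.0).  `"H-MP1"`, its analog with histidines replacing the lysines:
#' 2 Asp (4.0), 3 His (6.5), N-terminus (8.0).  Both peptides are C-terminally
#' amidated, so the C-terminus is not titratable.
#'
#' @param name `"MP1"` or `"H-MP1"`.
#' @param nterm_fixed If `TRUE`, pin the N-terminus fully protonated (as
#'   constant-pH MD protocols commonly do); default `FALSE` (titratable).
#' @return A [peptide_model()].
#' @examples
#' peptide_preset("MP1")
#' @export
peptide_preset <- function(name = c("MP1", "H-MP1"), nterm_fixed = FALSE) {
  name <- match.arg(name)
  basic <- if (name == "MP1") ionizable_site("Lys", "base", 3L, 10.4)
           else ionizable_site("His", "base", 3L, 6.5)
  peptide_model(name, list(
    ionizable_site("Asp", "acid", 2L, 4.0),
    basic,
    ionizable_site("Nterm", "base", 1L, 8.0, fixed_protonated = nterm_fixed)))
}

#' Potential-modified Henderson-Hasselbalch protonation fraction
#'
#' Fraction of a titratable site in the protonated state at a given pH and
#' local electrostatic potential:
#' `f = 1 / (1 + 10^(pH + log10(e) * F * psi / (R * T) - pKa))`.
#' A negative potential enriches protons locally and raises the protonation
#' fraction.
#'
#' @param pH Local pH (bulk or surface, depending on the modelling choice).
#' @param psi_V Local electrostatic potential in volts.
#' @param pKa Reference pKa of the site.
#' @param temperature_K Temperature in kelvin.
#' @return Protonation fraction in (0, 1).  Vectorized over its arguments.
#' @examples
#' protonation_fraction(7.4, -0.047, 6.5)  # histidine, about 44% protonated
#' @export
protonation_fraction <- function(pH, psi_V = 0, pKa, temperature_K = 298.15) {
  expo <- pH + log10(exp(1)) * .kc$F * psi_V / (.kc$R * temperature_K) - pKa
  1 / (1 + 10^expo)
}

#' Invert the potential-modified Henderson-Hasselbalch relation
#'
#' Given an observed protonation fraction, the pH and the reference pKa,
#' returns the local electrostatic potential that produces it:
#' `psi = (pKa - pH + log10((1-f)/f)) * ln(10) * R * T / F`.
#' Exact inverse of [protonation_fraction()] at fixed `(pH, pKa)`.
#'
#' @param f Protonation fraction, strictly in (0, 1).
#' @param pH Local pH.
#' @param pKa Reference pKa.
#' @param temperature_K Temperature in kelvin.
#' @return Potential in volts.
#' @examples
#' # aspartate 59% protonated at pH 5.5 implies it feels about -98 mV
#' 1e3 * potential_from_fraction(0.59, 5.5, 4.0)
#' @export
potential_from_fraction <- function(f, pH, pKa, temperature_K = 298.15) {
  if (any(f <= 0) || any(f >= 1))
    stop("f must be strictly inside (0, 1); the potential is unbounded at 0/1")
  (pKa - pH + log10((1 - f) / f)) * log(10) * .kc$R * temperature_K / .kc$F
}

#' Per-site protonation fractions of a peptide model
#'
#' @param model A [peptide_model()].
#' @param pH Local pH.
#' @param psi_V Local potential in volts.
#' @param temperature_K Temperature in kelvin.
#' @return Named numeric vector of protonation fractions, one per site.
#' @export
site_fractions <- function(model, pH, psi_V = 0, temperature_K = 298.15) {
  stopifnot(inherits(model, "peptide_model"))
  f <- vapply(model$sites, function(s) {
    if (s$fixed_protonated) 1
    else protonation_fraction(pH, psi_V, s$pKa_ref, temperature_K)
  }, numeric(1))
  names(f) <- vapply(model$sites, `[[`, character(1), "name")
  f
}

#' Peptide net charge from charge regulation
#'
#' Sums the site contributions: each base site contributes `+count * f` and
#' each acid site `-count * (1 - f)`, with `f` the potential-modified
#' protonation fraction of the site.  The result is bounded between minus the
#' total acid count and plus the total base count and decreases with pH.
#'
#' @inheritParams site_fractions
#' @return Net charge in elementary charges.  Vectorized over `pH`/`psi_V`.
#' @examples
#' mp1 <- peptide_preset("MP1")
#' peptide_net_charge(mp1, pH = 4.7, psi_V = -0.0403)  # about 2.98
#' @export
peptide_net_charge <- function(model, pH, psi_V = 0, temperature_K = 298.15) {
  stopifnot(inherits(model, "peptide_model"))
  z <- 0
  for (s in model$sites) {
    f <- if (s$fixed_protonated) 1
         else protonation_fraction(pH, psi_V, s$pKa_ref, temperature_K)
    z <- z + if (s$kind == "base") s$count * f else -s$count * (1 - f)
  }
  z
}
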