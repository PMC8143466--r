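#' Hill titration curve
#'
#' Protonation fraction as a function of pH with cooperativity:
#' `f = 1 / (1 + 10^(n * (pH - pKa)))`.  Decreasing in pH, `f = 0.5` at
#' `pH = pKa`; `n = 1` recovers the plain Henderson-Hasselbalch curve and
#' the slope at the midpoint is `-n * ln(10) / 4`.
#'
#' @param pH pH values.
#' @param pKa Midpoint of the titration.
#' @param n Hill coefficient (> 0).
#' @return Protonation fraction(s) in (0, 1).
#' @export
hill_model <- function(pH, pKa, n) {
  if (any(n <= 0)) stop("Hill coefficient n must be > 0")
  1 / (1 + 10^(n * (pH - pKa)))
}

#' Fit the Hill equation to per-residue protonation fractions
#'
#' Weighted nonlinear least squares of [hill_model()] against
#' `(pH, fraction)` points, typically the constant-pH MD protonation
#' fractions of one residue in one environment.  Weights are
#' inverse-variance from the supplied standard deviations; if any SD is
#' zero or missing the fit falls back to unweighted least squares (tabulated
#' SDs of well-sampled saturated points are often exactly 0).
#'
#' @param pH pH values (>= 2 points).
#' @param fraction Protonation fractions in `[0, 1]`.
#' @param sd Optional standard deviations of the fractions.
#' @return An object of class `hill_fit`: `pKa`, `pKa_sd`, `n`, `n_sd`,
#'   `residuals`, `weighted`, `data`.
#' @examples
#' f <- hill_model(c(5, 6, 7, 8), pKa = 6.2, n = 1.4)
#' fit_hill(c(5, 6, 7, 8), f)
#' @export
fit_hill <- function(pH, fraction, sd = NULL) {
  if (length(pH) < 2L || length(fraction) != length(pH))
    stop("need >= 2 matched (pH, fraction) points")
  if (any(fraction < 0 | fraction > 1)) stop("fractions must be in [0, 1]")
  if (max(fraction) < 0.02 || min(fraction) > 0.98)
    stop("titration not bracketed: all fractions saturated")
  weighted <- !is.null(sd) && all(is.finite(sd)) && all(sd > 0)
  w <- if (weighted) 1 / sd^2 else rep(1, length(pH))
  # midpoint start: pH of the point closest to f = 0.5
  start <- list(pKa = pH[which.min(abs(fraction - 0.5))], n = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ 1 / (1 + 10^(n * (pH - pKa))),
                      start = start, weights = w,
                      lower = c(pKa = -5, n = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit failed: ", conditionMessage(e)))
  co <- summary(fit)$coefficients
  structure(list(pKa = co["pKa", "Estimate"], pKa_sd = co["pKa", "Std. Error"],
                 n = co["n", "Estimate"], n_sd = co["n", "Std. Error"],
                 residuals = stats::residuals(fit), weighted = weighted,
                 data = data.frame(pH = pH, fraction = fraction)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: pKa %.3f +/- %.3f, n %.2f +/- %.2f (%sweighted)\n",
              x$pKa, x$pKa_sd, x$n, x$n_sd, if (x$weighted) "" else "un"))
  invisible(x)
}

#' pKa shift between two environments
#'
#' Difference of fitted pKa values (e.g. membrane-adsorbed minus aqueous
#' solution) with the uncertainty propagated in quadrature.  The baseline
#' may be another [fit_hill()] result or a plain reference pKa number (used
#' when the solution-state titration is too saturated to fit, as for
#' aspartates that are essentially deprotonated in water).
#'
#' @param fit_target A `hill_fit` for the environment of interest.
#' @param baseline A `hill_fit` or a single numeric reference pKa.
#' @return List with `delta` and `sd`.  Antisymmetric in its arguments.
#' @export
delta_pka <- function(fit_target, baseline) {
  stopifnot(inherits(fit_target, "hill_fit"))
  if (inherits(baseline, "hill_fit")) {
    list(delta = fit_target$pKa - baseline$pKa,
         sd = sqrt(fit_target$pKa_sd^2 + baseline$pKa_sd^2))
  } else {
    stopifnot(is.numeric(baseline), length(baseline) == 1L)
    list(delta = fit_target$pKa - baseline, sd = fit_target$pKa_sd)
  }
}

#' Classify proton-binding cooperativity from the Hill coefficient
#'
#' `n > 1 + tol` means protonation of one site favors protonation of
#' another (cooperative); `n < 1 - tol` anti-cooperative; otherwise the
#' sites titrate independently.
#'
#' @param fit A [fit_hill()] result.
#' @param tolerance Half-width of the "independent" band around 1.
#' @return One of `"cooperative"`, `"independent"`, `"anti-cooperative"`.
#' @export
classify_cooperativity <- function(fit, tolerance = 0.1) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$n > 1 + tolerance) "cooperative"
  else if (fit$n < 1 - tolerance) "anti-cooperative"
  else "independent"
}

# residue name -> acid/base (N-terminus handled separately)
.residue_kind <- function(residue) {
  r <- toupper(substr(residue, 1, 3))
  if (r %in% c("ASP", "GLU")) "acid"
  else if (r %in% c("LYS", "HIS", "ARG")) "base"
  else stop("unknown residue kind for '", residue, "'")
}

#' Net charge from tabulated per-residue protonation fractions
#'
#' Sums simulated protonation fractions into a peptide net charge:
#' bases contribute `+f`, acids `-(1 - f)`, and a protonation-pinned
#' N-terminus contributes `+1` (constant-pH MD protocols commonly hold it
#' protonated).  The standard deviation combines the per-residue SDs in
#' quadrature.
#'
#' @param table Data frame with columns `residue`, `pH`, `fraction`, `sd`
#'   (the schema of [cphmd_fractions()], one peptide and environment).
#' @param pH The pH at which to evaluate the charge (must match rows).
#' @param nterm_fixed Add `+1` for a pinned protonated N-terminus.
#' @return List with `zp` and `sd`.
#' @examples
#' tab <- subset(cphmd_fractions(), peptide == "MP1" & environment == "adsorbed")
#' cphmd_net_charge(tab, pH = 5.5)  # about 3.17
#' @export
cphmd_net_charge <- function(table, pH, nterm_fixed = TRUE) {
  stopifnot(is.data.frame(table),
            all(c("residue", "pH", "fraction") %in% names(table)))
  rows <- table[abs(table$pH - pH) < 1e-9, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no fractions tabulated at pH ", pH)
  kinds <- vapply(rows$residue, .residue_kind, character(1))
  contrib <- ifelse(kinds == "base", rows$fraction, -(1 - rows$fraction))
  sds <- if ("sd" %in% names(rows)) rows$sd else rep(0, nrow(rows))
  list(zp = sum(contrib) + if (nterm_fixed) 1 else 0,
       sd = sqrt(sum(sds^2)))
}

#' Bundled constant-pH MD protonation fractions for MP1 and H-MP1
#'
#' Per-residue protonation fractions (with standard errors) of the
#' titratable residues of MP1 and H-MP1 at pH 5.5, 6.5 and 7.4, in aqueous
#' solution and adsorbed on a 7POPC:3POPG bilayer, as tabulated from
#' constant-pH molecular dynamics.
#'
#' @return Data frame with columns `peptide`, `environment`
#'   (`"solution"`/`"adsorbed"`), `residue`, `pH`, `fraction`, `sd`.
#' @export
cphmd_fractions <- function() {
  path <- system.file("extdata", "cphmd_protonation_fractions.csv",
                      package = "gcreg", mustWork = TRUE)
  read_protonation_csv(path)
}

#' Hill-equation pKa report across residues and environments
#'
#' For every peptide/residue in a protonation table, fits the Hill equation
#' in the adsorbed environment and, where the solution-state titration is
#' informative, in solution too.  The pKa shift is taken against the
#' solution fit when available and against the residue's reference pKa
#' otherwise (aspartate solution fractions are typically too close to zero
#' to constrain a fit).  Residues saturated in both environments (e.g.
#' lysines, always fully protonated) are skipped.
#'
#' @param table Data frame in the [cphmd_fractions()] schema.
#' @param reference_pKa Named vector of fallback reference pKa values by
#'   residue prefix.
#' @param cooperativity_tol Band half-width for [classify_cooperativity()].
#' @return Data frame with one row per fitted residue: `peptide`, `residue`,
#'   `pKa`, `pKa_sd`, `n`, `n_sd`, `delta_pKa`, `delta_sd`, `baseline`
#'   (`"solution"` or `"reference"`), `cooperativity`.
#' @export
hill_pka_report <- function(table,
                            reference_pKa = c(Asp = 4.0, Glu = 4.0,
                                              His = 6.5, Lys = 10.4),
                            cooperativity_tol = 0.1) {
  out <- list()
  for (pep in unique(table$peptide)) {
    tp <- table[table$peptide == pep, , drop = FALSE]
    for (res in unique(tp$residue)) {
      ads <- tp[tp$residue == res & tp$environment == "adsorbed", ]
      sol <- tp[tp$residue == res & tp$environment == "solution", ]
      fit_ads <- tryCatch(fit_hill(ads$pH, ads$fraction, ads$sd),
                          error = function(e) NULL)
      if (is.null(fit_ads)) next
      fit_sol <- if (nrow(sol) >= 2L)
        tryCatch(fit_hill(sol$pH, sol$fraction, sol$sd),
                 error = function(e) NULL) else NULL
      if (!is.null(fit_sol)) {
        d <- delta_pka(fit_ads, fit_sol); base <- "solution"
      } else {
        ref <- reference_pKa[[substr(res, 1, 3)]]
        if (is.null(ref)) next
        d <- delta_pka(fit_ads, ref); base <- "reference"
      }
      out[[length(out) + 1L]] <- data.frame(
        peptide = pep, residue = res, pKa = fit_ads$pKa,
        pKa_sd = fit_ads$pKa_sd, n = fit_ads$n, n_sd = fit_ads$n_sd,
        delta_pKa = d$delta, delta_sd = d$sd, baseline = base,
        cooperativity = classify_cooperativity(fit_ads, cooperativity_tol))
    }
  }
  do.call(rbind, out)
}
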