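#' Self-consistent Gouy-Chapman state at one adsorbed fraction
#'
#' Couples the surface-potential solver and charge regulation at a fixed
#' adsorbed peptide fraction `Xb`: the peptide net charge depends on the
#' surface potential through the protonation of its sites, and the potential
#' depends back on `Xb * zp` through the lipid charge density.  The fixed
#' point is found by damped iteration on `zp` (damping 0.5) with an exact
#' inner root-solve for `psi`, stopping when `|delta zp|` falls below
#' `tol_zp`.
#'
#' In `pH_mode = "surface"` the pH entering the Henderson-Hasselbalch
#' relation is the surface pH computed once from the unperturbed (`Xb = 0`)
#' potential, while the potential term in that relation tracks the current
#' `Xb`; this is the policy that reproduces the hand-worked adsorption
#' example (f_Asp 0.489, zp 2.978 at Xb 0.0167).  Set
#' `recompute_pHs = TRUE` to instead refresh the surface pH from the current
#' potential at every iteration (documented alternative; gives slightly
#' different fractions).  In `pH_mode = "bulk"` the bulk pH is used directly.
#'
#' @param membrane A [membrane_spec()].
#' @param solution A [solution_conditions()].
#' @param peptide A [peptide_model()].
#' @param Xb Adsorbed peptide per outer-leaflet lipid (>= 0).
#' @param pH_mode `"surface"` or `"bulk"`.
#' @param Cf_M Optional free peptide concentration to record in the state.
#' @param damping Damping factor for the zp update, in (0, 1].
#' @param tol_zp Convergence tolerance on the net charge.
#' @param max_iter Maximum iterations before failing.
#' @param recompute_pHs Refresh the surface pH each iteration (see Details).
#' @return An object of class `gc_state`: list with `Xb`, `Cf_M`, `psi_V`,
#'   `zp`, `pHs` (the pH used in the protonation relation), `site_fractions`,
#'   `pH_mode`, `iterations`, `converged`.
#' @examples
#' st <- self_consistent_state(membrane_spec(), solution_conditions(5.5),
#'                             peptide_preset("MP1"), Xb = 0.0167)
#' c(psi_mV = 1e3 * st$psi_V, zp = st$zp)
#' @export
self_consistent_state <- function(membrane, solution, peptide, Xb,
                                  pH_mode = c("surface", "bulk"), Cf_M = NA_real_,
                                  damping = 0.5, tol_zp = 1e-6, max_iter = 200L,
                                  recompute_pHs = FALSE) {
  pH_mode <- match.arg(pH_mode)
  stopifnot(Xb >= 0)
  TK <- solution$temperature_K
  psi_bare <- solve_surface_potential(membrane, solution, Xb = 0, zp = 0)
  pH_use <- if (pH_mode == "surface")
    surface_pH(solution$pH_bulk, psi_bare, TK) else solution$pH_bulk

  zp <- 0; psi <- psi_bare; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    psi <- solve_surface_potential(membrane, solution, Xb = Xb, zp = zp)
    if (recompute_pHs && pH_mode == "surface")
      pH_use <- surface_pH(solution$pH_bulk, psi, TK)
    zp_new <- peptide_net_charge(peptide, pH_use, psi, TK)
    if (abs(zp_new - zp) < tol_zp) { zp <- zp_new; converged <- TRUE; break }
    zp <- zp + damping * (zp_new - zp)
  }
  if (!converged)
    stop(sprintf(paste0("self-consistent state did not converge in %d ",
                        "iterations (last psi %.3f mV, zp %.4f)"),
                 max_iter, 1e3 * psi, zp))
  psi <- solve_surface_potential(membrane, solution, Xb = Xb, zp = zp)
  structure(list(Xb = Xb, Cf_M = Cf_M, psi_V = psi, zp = zp, pHs = pH_use,
                 site_fractions = site_fractions(peptide, pH_use, psi, TK),
                 pH_mode = pH_mode, iterations = it, converged = converged),
            class = "gc_state")
}

#' @export
print.gc_state <- function(x, ...) {
  cat(sprintf("gc_state: Xb %.4g, psi %.2f mV, zp %.3f, pH(used) %.2f [%s]\n",
              x$Xb, 1e3 * x$psi_V, x$zp, x$pHs, x$pH_mode))
  invisible(x)
}

# Solve Xb for one free concentration: Xb = Kint * Cf * exp(-zp e psi / kBT)
# with (psi, zp) the self-consistent state at that Xb.  Monotone in Xb.
.solve_Xb_at_Cf <- function(membrane, solution, peptide, Kint, Cf_M,
                            pH_mode, zp_fixed = NULL, ...) {
  if (Cf_M <= 0) return(0)
  TK <- solution$temperature_K
  enrich <- function(Xb) {
    # beyond the admissible potential range the surface is so strongly
    # repulsive that the Boltzmann enrichment is effectively zero
    tryCatch({
      if (is.null(zp_fixed)) {
        st <- self_consistent_state(membrane, solution, peptide, Xb,
                                    pH_mode = pH_mode, ...)
        exp(-st$zp * .kc$e * st$psi_V / (.kc$kB * TK))
      } else {
        psi <- solve_surface_potential(membrane, solution, Xb, zp_fixed)
        exp(-zp_fixed * .kc$e * psi / (.kc$kB * TK))
      }
    }, error = function(e) {
      if (grepl("outside", conditionMessage(e))) 0 else stop(e)
    })
  }
  g <- function(Xb) Xb - Kint * Cf_M * enrich(Xb)
  hi <- Kint * Cf_M * enrich(0)
  if (hi == 0) return(0)
  n_grow <- 0L
  while (g(hi) < 0 && n_grow < 60L) { hi <- 2 * hi; n_grow <- n_grow + 1L }
  stats::uniroot(g, c(0, hi), tol = 1e-14)$root
}

#' Theoretical adsorption isotherm from the coupled Gouy-Chapman model
#'
#' For each free peptide concentration `Cf` solves the simultaneous system
#' `Xb = Kint * Cf * exp(-zp * e * psi / (kB*T))` with `(psi, zp)` the
#' self-consistent charge-regulated state at that `Xb`.
#'
#' @inheritParams self_consistent_state
#' @param Kint Intrinsic adsorption constant in 1/M (> 0).
#' @param Cf_M Vector of free peptide concentrations in mol/L.
#' @param zp_fixed Optional fixed net charge: when supplied, charge
#'   regulation is bypassed and `zp` is held at this value while `psi` still
#'   tracks `Xb` (the conventional "average zp" reduction).
#' @param ... Passed to [self_consistent_state()].
#' @return A data frame with one row per `Cf` point: `Cf_M`, `Xb`, `psi_V`,
#'   `zp`, `pHs`.
#' @export
theoretical_isotherm <- function(membrane, solution, peptide, Kint, Cf_M,
                                 pH_mode = c("surface", "bulk"),
                                 zp_fixed = NULL, ...) {
  pH_mode <- match.arg(pH_mode)
  if (!is.numeric(Kint) || Kint <= 0) stop("Kint must be > 0")
  rows <- lapply(Cf_M, function(cf) {
    Xb <- .solve_Xb_at_Cf(membrane, solution, peptide, Kint, cf,
                          pH_mode, zp_fixed, ...)
    if (is.null(zp_fixed)) {
      st <- self_consistent_state(membrane, solution, peptide, Xb,
                                  pH_mode = pH_mode, Cf_M = cf, ...)
      data.frame(Cf_M = cf, Xb = Xb, psi_V = st$psi_V, zp = st$zp, pHs = st$pHs)
    } else {
      psi <- solve_surface_potential(membrane, solution, Xb, zp_fixed)
      pHs <- if (pH_mode == "surface")
        surface_pH(solution$pH_bulk,
                   solve_surface_potential(membrane, solution, 0, 0),
                   solution$temperature_K) else solution$pH_bulk
      data.frame(Cf_M = cf, Xb = Xb, psi_V = psi, zp = zp_fixed, pHs = pHs)
    }
  })
  do.call(rbind, rows)
}

#' Reduce a fluorescence titration to adsorption-isotherm points
#'
#' Converts fractional fluorescence intensities to bound and free peptide:
#' `Xb = Fn * CP / (L/2)` (adsorbed peptide per outer-leaflet lipid) and
#' `Cf = CP * (1 - Fn)`.  Mass balance `Cf + Xb * L/2 = CP` holds exactly.
#'
#' @param Fn Fractional fluorescence after each vesicle addition, in `[0, 1]`.
#' @param CP_M Total peptide concentration in mol/L.
#' @param L_total_M Total lipid concentration after each addition, mol/L.
#' @return Data frame with `L_total_M`, `Fn`, `Xb`, `Cf_M`.
#' @export
fluorescence_to_binding <- function(Fn, CP_M, L_total_M) {
  if (length(Fn) != length(L_total_M)) stop("Fn and L_total_M lengths differ")
  if (any(Fn < 0 | Fn > 1)) stop("Fn must be in [0, 1]")
  if (any(L_total_M <= 0 & Fn > 0))
    stop("zero lipid with non-zero bound fraction is inconsistent")
  data.frame(L_total_M = L_total_M, Fn = Fn,
             Xb = ifelse(L_total_M > 0, Fn * CP_M / (L_total_M / 2), 0),
             Cf_M = CP_M * (1 - Fn))
}

#' Average net charge over converged states
#'
#' @param states A list of `gc_state` objects, or a data frame with a `zp`
#'   column (as returned by [theoretical_isotherm()]).
#' @return List with `zp_mean`, `zp_sd` (0 for a single state) and `n`.
#' @export
average_net_charge <- function(states) {
  zp <- if (is.data.frame(states)) states$zp
        else vapply(states, `[[`, numeric(1), "zp")
  if (length(zp) == 0L) stop("no states supplied")
  list(zp_mean = mean(zp), zp_sd = if (length(zp) > 1L) stats::sd(zp) else 0,
       n = length(zp))
}

#' Fit the intrinsic adsorption constant to isotherm points
#'
#' Least-squares fit of the coupled Gouy-Chapman isotherm to observed
#' `(Cf, Xb)` points.  Following the usual reduction, the per-point
#' self-consistent states at the observed `Xb` are computed first and their
#' average net charge `<zp>` is then held fixed while `Kint` alone is
#' adjusted (set `fit_zp = TRUE` to co-fit `<zp>` as a free parameter).  The
#' loss is ordinary least squares on `Xb`.
#'
#' @param points Data frame with columns `Xb` and `Cf_M` (e.g. from
#'   [fluorescence_to_binding()]); at least 3 points.
#' @inheritParams self_consistent_state
#' @param fit_zp Co-fit the average net charge instead of fixing it.
#' @param zp_mode `"fixed_average"` (default): predict with the net charge
#'   held at `<zp>` while the potential tracks `Xb`; `"regulated"`: predict
#'   with full per-point charge regulation (slower, exactly matches
#'   [theoretical_isotherm()]).
#' @param ... Passed to [self_consistent_state()].
#' @return An object of class `gc_isotherm_fit`: `Kint`, `Kint_sd`,
#'   `zp_mean`, `zp_sd`, `states` (per-point), `fitted` (predicted Xb),
#'   `residuals`.
#' @export
fit_kint <- function(points, membrane, solution, peptide,
                     pH_mode = c("surface", "bulk"), fit_zp = FALSE,
                     zp_mode = c("fixed_average", "regulated"), ...) {
  pH_mode <- match.arg(pH_mode)
  zp_mode <- match.arg(zp_mode)
  stopifnot(is.data.frame(points), all(c("Xb", "Cf_M") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 isotherm points")
  if (length(unique(points$Cf_M)) < 2L)
    stop("degenerate data: all Cf values identical")

  states <- lapply(points$Xb, function(xb)
    self_consistent_state(membrane, solution, peptide, xb,
                          pH_mode = pH_mode, ...))
  zstat <- average_net_charge(states)

  pred <- function(Kint, zp_bar) vapply(points$Cf_M, function(cf)
    .solve_Xb_at_Cf(membrane, solution, peptide, Kint, cf, pH_mode,
                    zp_fixed = if (zp_mode == "regulated") NULL else zp_bar),
    numeric(1))
  ssr <- function(par) {
    K <- exp(par[1])
    z <- if (fit_zp) par[2] else zstat$zp_mean
    sum((points$Xb - pred(K, z))^2)
  }
  # initial Kint from the per-point enrichment at the observed states
  K0 <- stats::median(points$Xb /
    boltzmann_surface_conc(points$Cf_M, zstat$zp_mean,
                           vapply(states, `[[`, numeric(1), "psi_V"),
                           solution$temperature_K))
  if (!is.finite(K0) || K0 <= 0) K0 <- 1
  if (fit_zp) {
    opt <- stats::optim(c(log(K0), zstat$zp_mean), ssr, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    Kint <- exp(opt$par[1]); zp_bar <- opt$par[2]
  } else {
    opt <- stats::optimize(function(lk) ssr(lk), log(K0) + c(-8, 8),
                           tol = 1e-10)
    Kint <- exp(opt$minimum); zp_bar <- zstat$zp_mean
  }
  fitted <- pred(Kint, zp_bar)
  res <- points$Xb - fitted
  # Gauss-Newton standard error on Kint from the residual variance
  h <- Kint * 1e-4
  J <- (pred(Kint + h, zp_bar) - pred(Kint - h, zp_bar)) / (2 * h)
  dof <- max(nrow(points) - if (fit_zp) 2L else 1L, 1L)
  sigma2 <- sum(res^2) / dof
  Kint_sd <- sqrt(sigma2 / sum(J^2))
  structure(list(Kint = Kint, Kint_sd = Kint_sd, zp_mean = zp_bar,
                 zp_sd = zstat$zp_sd, states = states, fitted = fitted,
                 residuals = res, pH_mode = pH_mode, n = nrow(points)),
            class = "gc_isotherm_fit")
}

#' @export
print.gc_isotherm_fit <- function(x, ...) {
  cat(sprintf("Kint = %.4g +/- %.2g 1/M, <zp> = %.3f +/- %.3f (%d points, %s pH)\n",
              x$Kint, x$Kint_sd, x$zp_mean, x$zp_sd, x$n, x$pH_mode))
  invisible(x)
}
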