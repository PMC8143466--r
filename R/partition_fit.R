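#' Langmuir-type fluorescence partition model
#'
#' Normalized tryptophan fluorescence as a function of the outer-leaflet
#' lipid concentration:
#' `I/I0 = 1 + (Imax/I0 - 1) * Kp*gamma*L/2 / (1 + Kp*gamma*L/2)`.
#' The ratio rises from 1 at zero lipid to `Imax/I0` at full binding, with
#' half-saturation at `Kp * gamma * L/2 = 1`.
#'
#' @param L_half_M Outer-leaflet lipid concentration (half the total), mol/L.
#' @param Kp Partition constant (used with `gamma * L`).
#' @param Imax_over_I0 Intensity ratio at complete binding (>= 1 for
#'   intensity-increase systems).
#' @param gamma Lipid molar volume in L/mol; default 0.75.
#' @return Intensity ratio `I/I0`.
#' @export
partition_model <- function(L_half_M, Kp, Imax_over_I0, gamma = 0.75) {
  if (any(L_half_M < 0)) stop("L_half_M must be >= 0")
  x <- Kp * gamma * L_half_M
  1 + (Imax_over_I0 - 1) * x / (1 + x)
}

#' Fit the partition constant to a normalized fluorescence series
#'
#' Nonlinear least squares of [partition_model()] against `I/I0` vs total
#' lipid concentration (the outer-leaflet `L/2` is used internally).
#' Starting values: `Imax/I0` from the largest observed ratio, `Kp` from the
#' lipid concentration at half-maximal signal change.  Standard errors come
#' from the fit covariance; when the data show no curvature the `Kp` error
#' is large and the fit is flagged as poorly constrained.
#'
#' @param L_total_M Total lipid concentrations, mol/L (>= 4 points).
#' @param I_ratio Normalized intensities `I/I0`.
#' @param gamma Lipid molar volume in L/mol; default 0.75.
#' @return An object of class `partition_fit`: `Kp`, `Kp_sd`,
#'   `Imax_over_I0`, `Imax_sd`, `poorly_constrained` (relative `Kp` error
#'   above 50%), `fit` (the underlying `nls` object).
#' @examples
#' L <- seq(5e-5, 1.3e-3, length.out = 10)
#' y <- partition_model(L / 2, Kp = 1e4, Imax_over_I0 = 2.5)
#' fit_partition(L, y)$Kp
#' @export
fit_partition <- function(L_total_M, I_ratio, gamma = 0.75) {
  if (length(L_total_M) < 4L) stop("need at least 4 titration points")
  if (length(L_total_M) != length(I_ratio)) stop("input lengths differ")
  Lh <- L_total_M / 2
  Imax0 <- max(max(I_ratio), 1 + 1e-3)
  half_signal <- 1 + (Imax0 - 1) / 2
  iL <- which.min(abs(I_ratio - half_signal))
  Kp0 <- 1 / (gamma * max(Lh[iL], min(Lh[Lh > 0])))
  fit <- tryCatch(
    minpack.lm::nlsLM(I_ratio ~ 1 + (Imax - 1) * (Kp * gamma * Lh) /
                        (1 + Kp * gamma * Lh),
                      start = list(Kp = Kp0, Imax = Imax0),
                      lower = c(Kp = 1e-12, Imax = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("partition fit did not converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  structure(list(Kp = co["Kp", "Estimate"], Kp_sd = co["Kp", "Std. Error"],
                 Imax_over_I0 = co["Imax", "Estimate"],
                 Imax_sd = co["Imax", "Std. Error"],
                 poorly_constrained =
                   co["Kp", "Std. Error"] > 0.5 * co["Kp", "Estimate"],
                 gamma = gamma, fit = fit),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Kp = %.4g +/- %.2g, Imax/I0 = %.3f +/- %.3f%s\n",
              x$Kp, x$Kp_sd, x$Imax_over_I0, x$Imax_sd,
              if (x$poorly_constrained) "  [poorly constrained]" else ""))
  invisible(x)
}
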