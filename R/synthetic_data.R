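#' Ground-truth scenario for synthetic titrations
#'
#' Bundles everything the forward models need to emulate one experimental
#' condition: the peptide, the membrane, the bulk solution, the intrinsic
#' adsorption constant and the noise levels.  The defaults mirror the study
#' conditions: 2 uM peptide titrated with 7POPC:3POPG vesicles up to 1.3 mM
#' total lipid in 150 mM NaCl at 25 C.
#'
#' @param peptide `"MP1"` or `"H-MP1"` (preset name) or a [peptide_model()].
#' @param pH_bulk Bulk pH of the condition.
#' @param Kint Intrinsic adsorption constant in 1/M.
#' @param Kp Partition constant for the fluorescence-only (Langmuir) model.
#' @param Imax_over_I0 Saturation intensity ratio for the Langmuir model.
#' @param CP_M Total peptide concentration, mol/L.
#' @param L_max_M Maximum total lipid concentration, mol/L.
#' @param pH_mode `"surface"` or `"bulk"` protonation pH policy.
#' @param membrane A [membrane_spec()].
#' @param c_salt_M Salt concentration, mol/L.
#' @param temperature_K Temperature, K.
#' @param noise_fluor Multiplicative Gaussian noise sd on fluorescence
#'   (default 2%).
#' @param noise_zeta_mV Additive Gaussian noise sd on zeta potentials, mV.
#' @return An object of class `gc_scenario`.
#' @export
gc_scenario <- function(peptide = "MP1", pH_bulk = 5.5, Kint = 1000,
                        Kp = 1e4, Imax_over_I0 = 2.5, CP_M = 2e-6,
                        L_max_M = 1.3e-3, pH_mode = "surface",
                        membrane = membrane_spec(), c_salt_M = 0.15,
                        temperature_K = 298.15, noise_fluor = 0.02,
                        noise_zeta_mV = 2) {
  pep <- if (inherits(peptide, "peptide_model")) peptide
         else peptide_preset(peptide)
  structure(list(peptide = pep, pH_bulk = pH_bulk, Kint = Kint, Kp = Kp,
                 Imax_over_I0 = Imax_over_I0, CP_M = CP_M, L_max_M = L_max_M,
                 pH_mode = pH_mode, membrane = membrane, c_salt_M = c_salt_M,
                 temperature_K = temperature_K, noise_fluor = noise_fluor,
                 noise_zeta_mV = noise_zeta_mV),
            class = "gc_scenario")
}

#' The six default study conditions
#'
#' Two peptides at three bulk pHs.  MP1 adsorbs with an intrinsic constant
#' of about 1000 1/M in surface-pH mode at every pH; H-MP1 binds about
#' five-fold weaker (200 1/M) and loses almost all affinity at neutral pH.
#'
#' @return Named list of [gc_scenario()] objects.
#' @export
default_scenarios <- function() {
  cond <- expand.grid(pep = c("MP1", "H-MP1"), pH = c(5.5, 6.5, 7.4),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cond)), function(i) {
    gc_scenario(peptide = cond$pep[i], pH_bulk = cond$pH[i],
                Kint = if (cond$pep[i] == "MP1") 1000 else 200)
  })
  names(out) <- sprintf("%s_pH%.1f", cond$pep, cond$pH)
  out
}

.scenario_solution <- function(s)
  solution_conditions(s$pH_bulk, s$c_salt_M, s$temperature_K)

# noiseless titration states: solve the mass balance Cf + Xb*L/2 = CP
# jointly with the self-consistent adsorption model at each lipid addition
.titration_states <- function(scenario, L_total_M) {
  sol <- .scenario_solution(scenario)
  lapply(L_total_M, function(L) {
    g <- function(Xb) {
      Cf <- scenario$CP_M - Xb * L / 2
      if (Cf < 0) return(Xb)  # positive: over-depleted branch
      Xb - .solve_Xb_at_Cf(scenario$membrane, sol, scenario$peptide,
                           scenario$Kint, Cf, scenario$pH_mode)
    }
    hi <- scenario$CP_M / (L / 2)
    Xb <- stats::uniroot(g, c(0, hi), tol = 1e-13)$root
    st <- self_consistent_state(scenario$membrane, sol, scenario$peptide,
                                Xb, pH_mode = scenario$pH_mode,
                                Cf_M = scenario$CP_M - Xb * L / 2)
    st
  })
}

#' Simulate a noisy fluorescence titration with known ground truth
#'
#' Forward model: at each lipid addition the coupled Gouy-Chapman
#' adsorption model is solved together with the mass balance
#' `Cf + Xb * L/2 = CP`, giving the noiseless bound fraction
#' `Fn = 1 - Cf/CP`; multiplicative Gaussian noise (sd
#' `scenario$noise_fluor`) then emulates intensity noise.  Deterministic
#' under a fixed seed.
#'
#' @param scenario A [gc_scenario()].
#' @param n_points Number of vesicle additions (>= 4).
#' @param seed Integer seed.
#' @return Data frame with columns `pH`, `CP_M`, `L_total_M`, `Fn` (the
#'   titration CSV schema).  The noiseless truth is attached as attribute
#'   `"truth"` (data frame with `Fn_true`, `Xb_true`, `Cf_true`, `psi_V`,
#'   `zp`).
#' @export
gen_fluorescence_titration <- function(scenario, n_points = 12, seed = 1) {
  stopifnot(inherits(scenario, "gc_scenario"))
  if (n_points < 4) stop("n_points must be >= 4")
  L <- seq(scenario$L_max_M / n_points, scenario$L_max_M,
           length.out = n_points)
  states <- .titration_states(scenario, L)
  Cf <- vapply(states, `[[`, numeric(1), "Cf_M")
  Xb <- vapply(states, `[[`, numeric(1), "Xb")
  Fn_true <- 1 - Cf / scenario$CP_M
  Fn <- withr::with_seed(seed, {
    pmin(pmax(Fn_true * (1 + stats::rnorm(n_points, 0, scenario$noise_fluor)),
              0), 1)
  })
  out <- data.frame(pH = scenario$pH_bulk, CP_M = scenario$CP_M,
                    L_total_M = L, Fn = Fn)
  attr(out, "truth") <- data.frame(
    Fn_true = Fn_true, Xb_true = Xb, Cf_true = Cf,
    psi_V = vapply(states, `[[`, numeric(1), "psi_V"),
    zp = vapply(states, `[[`, numeric(1), "zp"))
  out
}

#' Simulate a zeta-potential titration with known ground truth
#'
#' For each peptide-to-outer-leaflet-lipid ratio the total peptide
#' concentration is `P/L * L/2`; the adsorption model partitions it between
#' bound and free, the self-consistent surface potential follows, and the
#' diffuse-layer decay ([zeta_from_surface()]) maps it to a zeta potential
#' at the shear plane, plus additive Gaussian noise.
#'
#' @param scenario A [gc_scenario()].
#' @param P_over_L Peptide-to-outer-leaflet-lipid ratios (>= 0).
#' @param L_total_M Total lipid concentration of the vesicle suspension
#'   (default 40 uM, the typical electrophoresis condition).
#' @param x_shear_A Shear-plane distance in angstrom (default 3.7).
#' @param noise_mV Additive noise sd in mV (`NULL`: scenario default).
#' @param seed Integer seed.
#' @param DH_nm Vesicle hydrodynamic diameter to record, nm.
#' @return Data frame with `P_over_L_half`, `zeta_mV`, `DH_nm`, `pH`;
#'   noiseless truth (`zeta_true_mV`, `psi_V`, `Xb`, `zp`) as attribute
#'   `"truth"`.
#' @export
gen_zeta_titration <- function(scenario, P_over_L, L_total_M = 4e-5,
                               x_shear_A = 3.7, noise_mV = NULL, seed = 1,
                               DH_nm = 115) {
  stopifnot(inherits(scenario, "gc_scenario"))
  if (any(P_over_L < 0)) stop("P_over_L must be >= 0")
  if (is.null(noise_mV)) noise_mV <- scenario$noise_zeta_mV
  sol <- .scenario_solution(scenario)
  kap <- debye_kappa(sol)
  states <- lapply(P_over_L, function(r) {
    sc <- scenario; sc$CP_M <- r * L_total_M / 2
    if (sc$CP_M == 0)
      return(self_consistent_state(sc$membrane, sol, sc$peptide, 0,
                                   pH_mode = sc$pH_mode, Cf_M = 0))
    .titration_states(sc, L_total_M)[[1]]
  })
  psi <- vapply(states, `[[`, numeric(1), "psi_V")
  zeta_true <- zeta_from_surface(psi, kap, x_shear_A * 1e-10,
                                 scenario$temperature_K)
  zeta <- withr::with_seed(seed, {
    zeta_true + stats::rnorm(length(psi), 0, noise_mV * 1e-3)
  })
  out <- data.frame(P_over_L_half = P_over_L, zeta_mV = 1e3 * zeta,
                    DH_nm = DH_nm, pH = scenario$pH_bulk)
  attr(out, "truth") <- data.frame(
    zeta_true_mV = 1e3 * zeta_true, psi_V = psi,
    Xb = vapply(states, `[[`, numeric(1), "Xb"),
    zp = vapply(states, `[[`, numeric(1), "zp"))
  out
}

#' Simulate a constant-pH-MD-style protonation table
#'
#' Per-residue protonated fractions drawn binomially around a Hill-curve
#' ground truth, `SD = sqrt(f*(1-f)/n_samples)` (the sampling noise of
#' counting protonated frames), for one environment of one peptide.
#'
#' @param truth Data frame with columns `residue`, `pKa`, `n` (the Hill
#'   ground truth per residue).
#' @param pH pH values to sample at.
#' @param n_samples Number of binomial samples per (residue, pH) (>= 1).
#' @param seed Integer seed.
#' @param peptide,environment Labels for the output table.
#' @return Data frame in the [cphmd_fractions()] schema.
#' @export
gen_protonation_table <- function(truth, pH = c(5.5, 6.5, 7.4),
                                  n_samples = 1e4, seed = 1,
                                  peptide = "synthetic",
                                  environment = "adsorbed") {
  stopifnot(is.data.frame(truth),
            all(c("residue", "pKa", "n") %in% names(truth)))
  if (n_samples < 1) stop("n_samples must be >= 1")
  grid <- expand.grid(i = seq_len(nrow(truth)), pH = pH)
  f_true <- hill_model(grid$pH, truth$pKa[grid$i], truth$n[grid$i])
  f_obs <- withr::with_seed(seed, {
    stats::rbinom(nrow(grid), n_samples, f_true) / n_samples
  })
  data.frame(peptide = peptide, environment = environment,
             residue = truth$residue[grid$i], pH = grid$pH,
             fraction = f_obs, sd = sqrt(f_true * (1 - f_true) / n_samples))
}
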