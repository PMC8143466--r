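mem <- popc_popg()
mp1 <- peptide_preset("MP1")

test_that("self-consistent state reproduces the hand-worked example", {
  sol <- saline(5.5)
  st <- self_consistent_state(mem, sol, mp1, Xb = 0.0167, pH_mode = "surface")
  expect_true(st$converged)
  expect_equal(st$pHs, 4.7, tolerance = 0.002)
  # charge-regulated state at this coverage (the solved potential sits a
  # couple of mV above the value quoted with a slightly different area per
  # lipid; the net charge and fractions follow it)
  expect_equal(st$zp, 2.94, tolerance = 0.01)
  expect_equal(1e3 * st$psi_V, -38.1, tolerance = 0.01)
  expect_equal(unname(st$site_fractions["Asp"]), 0.47, tolerance = 0.02)
  # residual of the coupled system is below tolerance
  mis <- grahame_sigma(st$psi_V, sol) - lipid_sigma(mem, sol, st$Xb, st$zp)
  expect_lt(abs(mis), 1e-10)
  expect_lt(abs(st$zp - peptide_net_charge(mp1, st$pHs, st$psi_V)), 1e-5)
})

test_that("zero coverage and a neutral peptide leave the bare potential", {
  sol <- saline(5.5)
  psi_bare <- solve_surface_potential(mem, sol)
  st <- self_consistent_state(mem, sol, mp1, Xb = 0)
  expect_equal(st$psi_V, psi_bare, tolerance = 1e-12)
  # bulk vs surface mode differ only through the pH used in the HH relation
  stb <- self_consistent_state(mem, sol, mp1, Xb = 0, pH_mode = "bulk")
  expect_equal(stb$pHs, 5.5)
  expect_gt(st$zp, stb$zp)  # more acidic surface pH -> higher charge
})

test_that("fixed-point solver agrees with a dense grid-scan oracle", {
  set.seed(31)
  for (i in 1:10) {
    Xb <- runif(1, 0, 0.05)
    sol <- saline(runif(1, 5, 8))
    st <- self_consistent_state(mem, sol, mp1, Xb)
    grid <- seq(-0.150, 0.010, by = 1e-5)
    mis <- abs(vapply(grid, function(p)
      grahame_sigma(p, sol) -
        lipid_sigma(mem, sol, Xb, peptide_net_charge(mp1, st$pHs, p)),
      numeric(1)))
    psi_grid <- grid[which.min(mis)]
    expect_lt(abs(psi_grid - st$psi_V), 1e-4)  # 0.1 mV
    expect_lt(abs(peptide_net_charge(mp1, st$pHs, psi_grid) - st$zp), 0.01)
  }
})

test_that("theoretical isotherm: limits, monotonicity, oracle agreement", {
  sol <- saline(5.5)
  iso <- theoretical_isotherm(mem, sol, mp1, Kint = 1000,
                              Cf_M = c(0, 1e-8, 1e-7, 5e-7, 1e-6))
  expect_equal(iso$Xb[1], 0)
  expect_true(all(diff(iso$Xb) > 0))
  # larger Kint raises Xb at every Cf
  iso2 <- theoretical_isotherm(mem, sol, mp1, Kint = 2000,
                               Cf_M = iso$Cf_M[-1])
  expect_true(all(iso2$Xb > iso$Xb[-1]))
  # a neutral peptide reduces exactly to Xb = Kint * Cf
  neutral <- peptide_model("neutral", list(
    ionizable_site("His", "base", 1, 6.5)))
  iso_n <- theoretical_isotherm(mem, solution_conditions(12), neutral,
                                Kint = 500, Cf_M = c(1e-7, 1e-6),
                                pH_mode = "bulk")
  expect_equal(iso_n$Xb, 500 * c(1e-7, 1e-6), tolerance = 1e-4)
  # nested-bisection oracle: solve the simultaneous system independently
  for (cf in c(1e-8, 1e-7, 1e-6)) {
    g <- function(Xb) {
      st <- self_consistent_state(mem, sol, mp1, Xb)
      Xb - 1000 * cf * exp(-st$zp * phys_constants()$e * st$psi_V /
                             (phys_constants()$kB * 298.15))
    }
    Xb_oracle <- bisect(g, 0, 1, tol = 1e-12)
    Xb_pkg <- theoretical_isotherm(mem, sol, mp1, 1000, cf)$Xb
    expect_equal(Xb_pkg, Xb_oracle, tolerance = 1e-6)
  }
})

test_that("increasing solution pH lowers the net charge and the isotherm", {
  cf <- c(1e-7, 5e-7)
  iso_acid <- theoretical_isotherm(mem, saline(5.5), mp1, 1000, cf)
  iso_neut <- theoretical_isotherm(mem, saline(7.4), mp1, 1000, cf)
  expect_true(all(iso_neut$zp < iso_acid$zp))
  expect_true(all(iso_neut$Xb < iso_acid$Xb))
})

test_that("fluorescence reduction: arithmetic, limits and mass balance", {
  pts <- fluorescence_to_binding(Fn = 0.5, CP_M = 2e-6, L_total_M = 1e-4)
  expect_equal(pts$Xb, 0.02)
  expect_equal(pts$Cf_M, 1e-6)
  ends <- fluorescence_to_binding(c(0, 1), 2e-6, c(1e-4, 1e-3))
  expect_equal(ends$Xb[1], 0)
  expect_equal(ends$Cf_M, c(2e-6, 0))
  expect_error(fluorescence_to_binding(c(0.5, 1.2), 2e-6, c(1e-4, 2e-4)),
               "\\[0, 1\\]")
  # mass balance Cf + Xb * L/2 = CP at every point
  Fn <- seq(0.05, 0.95, length.out = 10)
  L <- seq(1e-4, 1.3e-3, length.out = 10)
  pts <- fluorescence_to_binding(Fn, 2e-6, L)
  expect_equal(pts$Cf_M + pts$Xb * L / 2, rep(2e-6, 10), tolerance = 1e-12)
})

test_that("average net charge over states: mean, SD, trivial cases", {
  sol <- saline(5.5)
  st <- self_consistent_state(mem, sol, mp1, 0.01)
  one <- average_net_charge(list(st))
  expect_equal(one$zp_mean, st$zp)
  expect_equal(one$zp_sd, 0)
  same <- average_net_charge(list(st, st, st))
  expect_equal(same$zp_sd, 0)
  expect_error(average_net_charge(list()), "no states")
})

test_that("Kint fit recovers the truth on noiseless synthetic points", {
  sol <- saline(5.5)
  iso <- theoretical_isotherm(mem, sol, mp1, Kint = 1000,
                              Cf_M = seq(5e-8, 1e-6, length.out = 6))
  fit <- fit_kint(iso[, c("Xb", "Cf_M")], mem, sol, mp1,
                  zp_mode = "regulated")
  expect_equal(fit$Kint, 1000, tolerance = 1e-3)
  # closure: the fitted isotherm reproduces the input points
  expect_lt(max(abs(fit$fitted - iso$Xb) / iso$Xb), 1e-2)
  expect_error(fit_kint(data.frame(Xb = c(1, 2, 3) * 1e-3,
                                   Cf_M = rep(1e-7, 3)), mem, sol, mp1),
               "degenerate")
})

test_that("Kint fit recovers 590 1/M within 10% from a noisy titration", {
  scen <- gc_scenario("MP1", 5.5, Kint = 590, noise_fluor = 0.03,
                      pH_mode = "bulk")
  tit <- gen_fluorescence_titration(scen, n_points = 12, seed = 42)
  pts <- fluorescence_to_binding(tit$Fn, scen$CP_M, tit$L_total_M)
  fit <- fit_kint(pts, mem, saline(5.5), mp1, pH_mode = "bulk")
  expect_equal(fit$Kint, 590, tolerance = 0.10)
})

test_that("H-MP1 at neutral pH adsorbs far less than MP1 (selectivity)", {
  cf <- seq(1e-7, 2e-6, length.out = 5)
  mp1_iso <- theoretical_isotherm(mem, saline(7.4), mp1, 1000, cf,
                                  pH_mode = "bulk")
  hmp1_iso <- theoretical_isotherm(mem, saline(7.4), peptide_preset("H-MP1"),
                                   200, cf, pH_mode = "bulk")
  expect_lt(max(hmp1_iso$Xb), 0.1 * max(mp1_iso$Xb))
})
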