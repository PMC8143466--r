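test_that("Debye screening length matches the closed form and scales as sqrt(c)", {
  sol <- saline(7)
  k <- debye_kappa(sol)
  # independent evaluation of kappa^2 = 2e3 NA e^2 c / (eps0 eps_r kB T)
  cst <- phys_constants()
  k_ref <- sqrt(2e3 * cst$N_A * cst$e^2 * 0.15 /
                  (cst$eps0 * 78.5 * cst$kB * 298.15))
  expect_equal(k, k_ref, tolerance = 1e-12)
  expect_equal(1e10 / k, 7.855, tolerance = 1e-3)  # about 7.9 A at 150 mM
  sol4 <- solution_conditions(7, c_salt_M = 4 * 0.15)
  expect_equal(debye_kappa(sol4), 2 * k, tolerance = 1e-12)
  expect_error(solution_conditions(7, c_salt_M = 0), "c_salt_M")
})

test_that("Grahame charge density: sign, parity, magnitude and linearization", {
  sol <- saline(7)
  expect_identical(grahame_sigma(0, sol), 0)
  expect_equal(grahame_sigma(0.02, sol), -grahame_sigma(-0.02, sol))
  # hand evaluation of sqrt(8000 eps0 eps_r R T C) * sinh(e psi / 2 kB T)
  cst <- phys_constants()
  pref <- sqrt(8000 * cst$eps0 * 78.5 * cst$R * 298.15 * 0.15)
  psi <- -0.047
  expect_equal(grahame_sigma(psi, sol),
               pref * sinh(cst$e * psi / (2 * cst$kB * 298.15)),
               tolerance = 1e-12)
  expect_equal(grahame_sigma(-0.047, sol), -0.0475, tolerance = 3e-3)
  # Debye-Hueckel linearization agrees to 1% for |psi| <= 10 mV
  for (p in c(-0.010, -0.005, 0.002, 0.010))
    expect_equal(grahame_sigma(p, sol) / grahame_sigma_linear(p, sol), 1,
                 tolerance = 0.01)
  expect_error(grahame_sigma(0.6, sol), "0.5")
})

test_that("lipid surface charge density follows (e/AL)(-XA + XNa + Xb zp)", {
  mem <- popc_popg(); sol <- saline(7)
  cst <- phys_constants()
  # XNa = KNa * CNa = 0.09 at 150 mM, so the bare density is (e/AL)(-0.21)
  expect_equal(lipid_sigma(mem, sol), (cst$e / 70e-20) * (-0.21),
               tolerance = 1e-12)
  expect_equal(lipid_sigma(mem, sol), -0.0481, tolerance = 1e-3)
  neutral <- membrane_spec(XA = 0, AL_A2 = 70, KNa_per_M = 0)
  expect_identical(lipid_sigma(neutral, sol), 0)
  # charge neutralization: Xb * zp = XA - XNa zeroes the density
  expect_equal(lipid_sigma(mem, sol, Xb = 0.07, zp = 3), 0, tolerance = 1e-12)
  expect_gt(lipid_sigma(mem, sol, Xb = 0.02, zp = 3),
            lipid_sigma(mem, sol, Xb = 0.01, zp = 3))
})

test_that("bare 7POPC:3POPG surface potential is about -47 mV", {
  psi0 <- solve_surface_potential(popc_popg(), saline(5.5))
  expect_equal(1e3 * psi0, -47, tolerance = 1 / 47)  # +/- 1 mV
})

test_that("surface-potential solver agrees with an independent bisection oracle", {
  mem <- popc_popg(); sol <- saline(5.5)
  for (case in list(c(0, 0), c(0.0167, 2.978), c(0.05, 2.0), c(0.1, 3.0))) {
    f <- function(p) grahame_sigma(p, sol) -
      lipid_sigma(mem, sol, Xb = case[1], zp = case[2])
    psi_oracle <- bisect(f, -0.3, 0.3)
    psi <- solve_surface_potential(mem, sol, Xb = case[1], zp = case[2])
    expect_lt(abs(psi - psi_oracle), 1e-8)  # < 0.01 mV
    expect_lt(abs(f(psi)), 1e-9)            # residual below tolerance
  }
  neutral <- membrane_spec(XA = 0, KNa_per_M = 0)
  expect_equal(solve_surface_potential(neutral, sol), 0)
})

test_that("solver round-trips Grahame on [-200, 200] mV and is monotone in Xb*zp", {
  sol <- saline(7); cst <- phys_constants()
  for (psi in seq(-0.2, 0.2, by = 0.05)) {
    # build a membrane whose bare density equals grahame_sigma(psi)
    sg <- grahame_sigma(psi, sol)
    XA_eff <- -sg * 70e-20 / cst$e  # -XA + XNa = sg * AL / e with KNa = 0
    if (abs(XA_eff) > 1) next
    mem <- membrane_spec(XA = abs(XA_eff), KNa_per_M = 0)
    target <- if (XA_eff >= 0) psi else NA
    if (!is.na(target))
      expect_equal(solve_surface_potential(mem, sol), psi, tolerance = 1e-9)
  }
  mem <- popc_popg()
  load <- seq(0, 0.2, by = 0.02)  # Xb * zp grid
  psis <- vapply(load, function(l)
    solve_surface_potential(mem, sol, Xb = l, zp = 1), numeric(1))
  expect_true(all(diff(psis) > 0))
})

test_that("outputs are invariant under unit-consistent rescaling of inputs", {
  sol <- saline(7)
  # AL enters only as e/AL: doubling AL halves sigma exactly
  m1 <- membrane_spec(AL_A2 = 70); m2 <- membrane_spec(AL_A2 = 140)
  expect_equal(lipid_sigma(m2, sol), lipid_sigma(m1, sol) / 2)
  # potential expressed in V; same physics if temperature passed consistently
  expect_equal(surface_pH(7, -0.047, 298.15),
               7 + phys_constants()$F * -0.047 /
                 (log(10) * phys_constants()$R * 298.15))
})

test_that("surface pH shifts acidic at negative potential by F psi / (ln10 RT)", {
  psi0 <- solve_surface_potential(popc_popg(), saline(5.5))
  expect_equal(surface_pH(5.5, psi0), 4.7, tolerance = 0.05 / 4.7)
  expect_equal(surface_pH(7.4, psi0), 6.6, tolerance = 0.05 / 6.6)
  expect_identical(surface_pH(6.2, 0), 6.2)
  expect_lt(surface_pH(6, -0.01), 6)
})

test_that("Boltzmann enrichment of peptide at the surface", {
  expect_identical(boltzmann_surface_conc(1e-6, 0, -0.05), 1e-6)
  expect_identical(boltzmann_surface_conc(1e-6, 3, 0), 1e-6)
  # zp 2.978 at -40.3 mV: enrichment about 1.07e2
  enr <- boltzmann_surface_conc(1e-6, 2.978, -0.0403) / 1e-6
  expect_equal(enr, 107, tolerance = 0.01)
  # sign flip of psi inverts enrichment symmetrically
  up <- boltzmann_surface_conc(1, 2, -0.03)
  dn <- boltzmann_surface_conc(1, 2, 0.03)
  expect_equal(up * dn, 1, tolerance = 1e-12)
})
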