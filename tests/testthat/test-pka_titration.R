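test_that("Hill curve: midpoint, HH reduction, midpoint slope n ln10 / 4", {
  expect_equal(hill_model(6.2, 6.2, 1.7), 0.5)
  # n = 1 is the plain Henderson-Hasselbalch curve at zero potential
  pH <- seq(3, 10, by = 0.5)
  expect_equal(hill_model(pH, 6.5, 1), protonation_fraction(pH, 0, 6.5))
  # steeper transition for larger n; slope at the midpoint is -n ln10 / 4
  for (n in c(0.8, 1, 1.5, 2.8)) {
    h <- 1e-6
    slope <- (hill_model(6 + h, 6, n) - hill_model(6 - h, 6, n)) / (2 * h)
    expect_equal(slope, -n * log(10) / 4, tolerance = 1e-6)
  }
  expect_error(hill_model(7, 6, -1), "n must be")
})

test_that("Hill fit recovers exact synthetic parameters", {
  pH <- c(5, 5.5, 6, 6.5, 7)
  f <- hill_model(pH, pKa = 6.0, n = 1.3)
  fit <- fit_hill(pH, f)
  expect_equal(fit$pKa, 6.0, tolerance = 1e-6)
  expect_equal(fit$n, 1.3, tolerance = 1e-6)
  expect_error(fit_hill(c(5, 6, 7), c(0.9999, 0.999, 0.998)),
               "not bracketed")
  expect_error(fit_hill(c(5, 6, 7), c(0.001, 0.0005, 0.0001)),
               "not bracketed")
})

test_that("Hill fits on the bundled adsorbed-state fractions match the reported pKas", {
  asp2 <- asp2_mp1_adsorbed()
  fit_asp2 <- fit_hill(asp2$pH, asp2$fraction, asp2$sd)
  expect_equal(fit_asp2$pKa, 5.53, tolerance = 0.06 / 5.53)
  his4 <- his4_hmp1_adsorbed()
  fit_his4 <- fit_hill(his4$pH, his4$fraction, his4$sd)
  expect_equal(fit_his4$pKa, 8.24, tolerance = 0.05 / 8.24)
  # solution-state histidine: cross-check against the two-point logit oracle
  his5 <- data.frame(pH = c(5.5, 6.5, 7.4),
                     fraction = c(0.7410, 0.2952, 0.0566))
  fit_his5 <- fit_hill(his5$pH, his5$fraction)
  logit10 <- function(f) log10((1 - f) / f)
  n_oracle <- (logit10(0.2952) - logit10(0.7410)) / 1.0
  pKa_oracle <- 5.5 - logit10(0.7410) / n_oracle
  expect_equal(fit_his5$pKa, pKa_oracle, tolerance = 0.15 / 6)
  expect_equal(fit_his5$pKa, 6.05, tolerance = 0.04 / 6.05)
})

test_that("binomial-noise Monte Carlo: Hill estimates are unbiased", {
  truth <- data.frame(residue = "X", pKa = 6.2, n = 1.4)
  est <- vapply(1:200, function(s) {
    tab <- gen_protonation_table(truth, pH = c(5, 5.5, 6, 6.5, 7, 7.5),
                                 n_samples = 2000, seed = s)
    fit_hill(tab$pH, tab$fraction, tab$sd)$pKa
  }, numeric(1))
  expect_lt(abs(mean(est) - 6.2), 0.01)
})

test_that("pKa shifts: mixed baselines and antisymmetry", {
  his4_ads <- with(his4_hmp1_adsorbed(), fit_hill(pH, fraction, sd))
  his4_sol <- fit_hill(c(5.5, 6.5, 7.4), c(0.4690, 0.1204, 0.0213),
                       c(0.0029, 0.0015, 0.0004))
  d <- delta_pka(his4_ads, his4_sol)
  expect_equal(d$delta, 2.80, tolerance = 0.08 / 2.80)
  # aspartate baseline falls back to the reference pKa 4.0
  asp2 <- with(asp2_mp1_adsorbed(), fit_hill(pH, fraction, sd))
  expect_equal(delta_pka(asp2, 4.0)$delta, 1.53, tolerance = 0.06 / 1.53)
  # antisymmetry
  d_ba <- delta_pka(his4_sol, his4_ads)
  expect_equal(d$delta, -d_ba$delta)
  expect_equal(delta_pka(his4_ads, his4_ads)$delta, 0)
})

test_that("cooperativity classification bands around n = 1", {
  his4 <- with(his4_hmp1_adsorbed(), fit_hill(pH, fraction, sd))
  expect_gt(his4$n, 1.1)
  expect_identical(classify_cooperativity(his4), "cooperative")
  fake <- his4; fake$n <- 1.0
  expect_identical(classify_cooperativity(fake), "independent")
  fake$n <- 0.6
  expect_identical(classify_cooperativity(fake), "anti-cooperative")
})

test_that("net charges from the bundled protonation tables match the tabulated values", {
  tab <- cphmd_fractions()
  expected <- data.frame(
    peptide = rep(c("MP1", "H-MP1"), each = 3),
    pH = rep(c(5.5, 6.5, 7.4), 2),
    zp = c(3.1713, 2.0874, 2.0084, 3.3162, 2.4503, 1.9046))
  for (i in seq_len(nrow(expected))) {
    sub <- tab[tab$peptide == expected$peptide[i] &
                 tab$environment == "adsorbed", ]
    z <- cphmd_net_charge(sub, expected$pH[i], nterm_fixed = TRUE)
    expect_equal(z$zp, expected$zp[i], tolerance = 0.001 / expected$zp[i])
  }
  # saturation: all bases protonated, all acids deprotonated
  sat <- data.frame(residue = c("Lys4", "Lys5", "Lys11", "Asp2", "Asp8"),
                    pH = 7, fraction = c(1, 1, 1, 0, 0), sd = 0)
  expect_equal(cphmd_net_charge(sat, 7)$zp, 3 + 1 - 2)
  expect_error(cphmd_net_charge(sat, 9), "no fractions")
})

test_that("the report fits every informative residue with the right baselines", {
  rep <- hill_pka_report(cphmd_fractions())
  expect_setequal(rep$residue[rep$peptide == "MP1"], c("Asp2", "Asp8"))
  expect_setequal(rep$residue[rep$peptide == "H-MP1"],
                  c("Asp2", "Asp8", "His4", "His5", "His11"))
  expect_true(all(rep$baseline[grepl("^Asp", rep$residue)] == "reference"))
  expect_true(all(rep$baseline[grepl("^His", rep$residue)] == "solution"))
  # reported pKa/shift values within their tabulated uncertainties
  ref <- data.frame(
    peptide = c("MP1", "MP1", "H-MP1", "H-MP1", "H-MP1", "H-MP1", "H-MP1"),
    residue = c("Asp2", "Asp8", "Asp2", "His4", "His5", "Asp8", "His11"),
    pKa = c(5.53, 5.65, 5.64, 8.24, 8.32, 6.05, 8.27),
    tol = c(0.06, 0.07, 0.05, 0.05, 0.19, 0.04, 0.03))
  m <- merge(rep, ref, by = c("peptide", "residue"))
  expect_equal(nrow(m), 7)
  expect_true(all(abs(m$pKa.x - m$pKa.y) <= m$tol + 1e-9))
  # adsorbed histidines titrate cooperatively (n about 1.5)
  his <- rep[grepl("^His", rep$residue), ]
  expect_true(all(his$cooperativity == "cooperative"))
})
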