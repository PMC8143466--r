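# shared fixtures for the test suite
popc_popg <- function() membrane_spec(XA = 0.3, AL_A2 = 70, KNa_per_M = 0.6)
saline <- function(pH) solution_conditions(pH, c_salt_M = 0.15)

# independent bisection root-finder used as oracle against the closed-form
# surface-potential solver
bisect <- function(f, lo, hi, tol = 1e-12, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# adsorbed-on-bilayer fractions of selected residues (fixture subset)
asp2_mp1_adsorbed <- function()
  data.frame(pH = c(5.5, 6.5, 7.4), fraction = c(0.5363, 0.0292, 0.0022),
             sd = c(0.0018, 0.0003, 0.0000))
his4_hmp1_adsorbed <- function()
  data.frame(pH = c(5.5, 6.5, 7.4), fraction = c(0.9999, 0.9981, 0.9536),
             sd = c(0.0000, 0.0001, 0.0008))
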