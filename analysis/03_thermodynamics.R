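#!/usr/bin/env Rscript
# Stage 2b -- equilibrium and transition-state energetics.
#
# Two parts. First, from the published van't Hoff / Eyring component
# tables (dH, -T dS at 25 C) it builds the delta-delta tables against wild
# type and the enthalpy-entropy compensation summary. Second, it
# demonstrates the fitting machinery itself on synthetic temperature
# series generated from the wild-type parameters: exact recovery at zero
# noise and small median bias at 5% multiplicative noise.
#
# What it finds: every improved mutein gains enthalpy (ddH < 0) both at
# equilibrium and in the transition state, almost fully compensated by
# entropy (compensation slope near -1); only ~5-11% of the enthalpy
# advantage survives as free energy.

suppressPackageStartupMessages(library(abmature))
dir.create("results", showWarnings = FALSE)
seed <- 1

kt <- load_published_tables("kinetics")
ch <- run_characterize(kt, load_published_tables("thermo"),
                       load_published_tables("activation"))

cat("equilibrium delta-delta table (kcal/mol at 25 C):\n")
print(ch$thermo_deltas, row.names = FALSE, digits = 3)
cat("\nactivation delta-delta table (kcal/mol at 25 C):\n")
print(ch$activation_deltas, row.names = FALSE, digits = 3)
cat(sprintf("\ncompensation: slope %.3f, r2 %.3f; efficiencies:\n",
            ch$compensation$slope, ch$compensation$r2))
print(ch$compensation$efficiencies, row.names = FALSE, digits = 2)
write_characterization(ch, "results/characterization")

## synthetic temperature-series recovery (the fitting test bed)
p <- data.frame(variant = "WT", dH = -7.3, dS = 5.0 / 298.15,
                dHa = 11.4, dSa = 0.8 / 298.15)
sim0 <- simulate_kinetics(p, T_grid = seq(283, 313, by = 5), cv = 0,
                          seed = seed)
vh <- vant_hoff_fit(sim0$T_K, sim0$KD)
ey <- eyring_fit(sim0$T_K, sim0$kon)
cat(sprintf("\nnoiseless recovery: dH %.4f (true %.1f), dHa %.4f (true %.1f)\n",
            vh$dH, p$dH, ey$dH, p$dHa))

est <- t(vapply(1:200, function(s) {
  sim <- simulate_kinetics(p, T_grid = seq(283, 313, by = 5), cv = 0.05,
                           seed = seed * 977 + s)
  c(vant_hoff_fit(sim$T_K, sim$KD)$dH, eyring_fit(sim$T_K, sim$kon)$dH)
}, numeric(2)))
cat(sprintf("5%% noise, 200 seeds: median dH %.3f, median dHa %.3f\n",
            median(est[, 1]), median(est[, 2])))
write.table(data.frame(seed = 1:200, dH = est[, 1], dHa = est[, 2]),
            "results/recovery_cv5.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
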