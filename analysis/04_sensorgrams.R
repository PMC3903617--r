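#!/usr/bin/env Rscript
# Stage 2c -- Langmuir 1:1 global sensorgram fitting.
#
# Simulates SPR sensorgram sets at the published wild-type rates
# (k_on 1.4e5 1/(M s), k_off 1.0e-4 1/s) over five analyte concentrations
# and fits k_on, k_off, R_max globally across all traces.
#
# What it finds: the global fit recovers the generating rates essentially
# exactly on noiseless traces and within a few percent at 2% RU noise.

suppressPackageStartupMessages(library(abmature))
dir.create("results", showWarnings = FALSE)
seed <- 1

kon <- 1.4e5; koff <- 1.0e-4; rmax <- 120
concs <- c(2, 5, 10, 20, 50) * 1e-9

sg <- simulate_sensorgram(kon, koff, rmax, concs, seed = seed)
f0 <- fit_sensorgram(sg)
cat(sprintf("noiseless: kon %.6g (true %.3g), koff %.6g (true %.3g), Rmax %.4g\n",
            f0$kon, kon, f0$koff, koff, f0$rmax))

sgn <- simulate_sensorgram(kon, koff, rmax, concs, noise_sd = 0.02 * rmax,
                           seed = seed)
fn <- fit_sensorgram(sgn)
cat(sprintf("2%% noise:  kon %.4g (+/- %.2g), koff %.4g (+/- %.2g), KD %.3g M\n",
            fn$kon, fn$se_kon, fn$koff, fn$se_koff, fn$kd))

fitted <- sgn
fitted$RU_fit <- abmature:::langmuir_response(sgn$t, sgn$conc, fn$kon,
                                              fn$koff, fn$rmax,
                                              sgn$t_assoc_end)
write.table(fitted, "results/sensorgram_fit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/sensorgram_fit.tsv (traces + fitted curves)\n")
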