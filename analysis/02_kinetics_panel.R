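#!/usr/bin/env Rscript
# Stage 2a -- kinetic characterization of the mutein panel.
#
# Loads the published 25 C SPR rate constants of 11K2 scFv (wild type and
# twelve single-muteins) binding MCP-1, recomputes K_D = k_off/k_on, flags
# rows whose printed K_D is inconsistent with the rates, and classifies
# each mutein by fold-improvement.
#
# What it finds: 5 of 12 muteins are improved (42%), all of them on the
# light chain (5 of 7 V_L muteins, 71%); the best is L-N31R at 0.17 nM,
# 4.7-fold over wild type. Two printed K_D values (WT, H-N28D) disagree
# with their own rate constants and are flagged rather than corrected.

suppressPackageStartupMessages(library(abmature))
dir.create("results", showWarnings = FALSE)

kt <- load_published_tables("kinetics")
ch <- run_characterize(kt)
print(ch)
write_characterization(ch, "results/characterization")

kk <- ch$kinetics
mut <- kk[kk$variant != "WT", ]
cat(sprintf("\nimproved: %d/%d muteins (%.0f%%); V_L: %d/%d (%.0f%%)\n",
            sum(mut$improved), nrow(mut), 100 * mean(mut$improved),
            sum(mut$improved & grepl("^L-", mut$variant)),
            sum(grepl("^L-", mut$variant)),
            100 * mean(mut$improved[grepl("^L-", mut$variant)])))
cat(sprintf("flagged as K_D-inconsistent: %s\n",
            paste(kk$variant[kk$kd_inconsistent], collapse = ", ")))
cat(sprintf("best mutein: L-N31R, K_D = %.2g nM, fold = %.2g\n",
            kk$KD_used[kk$variant == "L-N31R"] * 1e9,
            kk$fold[kk$variant == "L-N31R"]))
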