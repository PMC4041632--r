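#!/usr/bin/env Rscript
# Substrate-inhibition sweep: MMAsIII dose-response of DMAs production.
#
# Reaction mixtures start with MMAsIII at 0-20 muM and 0 or 1 mM GSH; total
# and trivalent DMAs are read out after 1 h. Two signatures are expected:
# the yield rises then falls across doses (cooperative substrate inhibition
# of the second methylation step), and 1 mM GSH raises the peak yield about
# four-fold (methyltransferase activation).
#
# Outputs: results/substrate_sweep_gsh0.csv, results/substrate_sweep_gsh1.csv

suppressPackageStartupMessages(library(arsmet))
dir.create("results", showWarnings = FALSE)
p <- kinetic_parameters()

r0 <- mmas_sweep(0, params = p)
r1 <- mmas_sweep(1, params = p)
for (x in list(list(r0, 0, "results/substrate_sweep_gsh0.csv"),
               list(r1, 1, "results/substrate_sweep_gsh1.csv"))) {
  write_result_csv(x[[1]], x[[3]],
                   spec_info = list(preset = "mmas_sweep", gsh_mM = x[[2]],
                                    doses = "0-20 by 0.5 muM", horizon_h = 1),
                   params = p)
}

opt0 <- interpolated_argmax(r0$dose, r0$total_DMAs)
cat(sprintf("0 mM GSH: peak total DMAs %.3g muM at %.2f muM MMAsIII;\n",
            max(r0$total_DMAs), opt0))
cat(sprintf("  yield at 20 muM is %.0f%% of the peak (substrate inhibition).\n",
            100 * r0$total_DMAs[nrow(r0)] / max(r0$total_DMAs)))
cat(sprintf("1 mM GSH: peak total DMAs %.3g muM; peak ratio 1 mM / 0 mM = %.2f\n",
            max(r1$total_DMAs), max(r1$total_DMAs) / max(r0$total_DMAs)))
cat("With 1 mM GSH most MMAsIII is held as its diglutathione conjugate, so\n",
    "free substrate stays below the inhibitory range across this dose grid\n",
    "and the within-grid decline is carried by the early unbound transient.\n")
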