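#!/usr/bin/env Rscript
# Parameter recovery on synthetic substrate-sweep assays.
#
# The inhibition constant KiM2 of the second methylation step is the one
# constant of the model that was originally obtained by fitting rather than
# measurement. Here synthetic sweeps (conjugate-blind readouts, proportional
# noise) are generated at the known truth and KiM2 is re-fitted, to show the
# assay design actually identifies it. Profile curves for Vmax and k10 on a
# GSH dose-response dataset illustrate which activation constants that
# design does and does not pin down.
#
# Outputs: results/recovery_kim2.csv, results/profile_activation.csv

suppressPackageStartupMessages(library(arsmet))
dir.create("results", showWarnings = FALSE)

truep <- kinetic_parameters()
des <- assay_design("mmas_sweep", gsh_mM = 0,
                    doses = c(0.5, 1, 2, 3, 5, 7, 10, 14, 20), horizon_h = 1)

## noise-free self-consistency -------------------------------------------------
ds0 <- generate_dataset(des, truep, cv = 0, seed = 1)
fit0 <- fit_to_dataset(ds0, "KiM2", bounds = list(KiM2 = c(1, 30)), seed = 1)
cat(sprintf("noise-free recovery: KiM2 = %.4f (truth %.1f, rel. err. %.2g)\n",
            fit0$fitted[["KiM2"]], truep$KiM2,
            abs(fit0$fitted[["KiM2"]] - truep$KiM2) / truep$KiM2))

## 20 replicates at 10% proportional noise -------------------------------------
reps <- do.call(rbind, lapply(1:20, function(i) {
  ds <- generate_dataset(des, truep, cv = 0.1, seed = 1000 + i)
  fit <- fit_to_dataset(ds, "KiM2", bounds = list(KiM2 = c(1, 30)),
                        seed = i, tol = 0.01)
  data.frame(replicate = i, seed = 1000 + i, KiM2_hat = fit$fitted[["KiM2"]],
             rel_error = abs(fit$fitted[["KiM2"]] - truep$KiM2) / truep$KiM2)
}))
write_result_csv(reps, "results/recovery_kim2.csv",
                 spec_info = list(analysis = "KiM2 recovery", cv = 0.1,
                                  design = unclass(des)),
                 params = truep)
cat(sprintf("20 replicates at cv 0.1: median KiM2 = %.3f, median rel. err. %.1f%%, max %.1f%%\n",
            median(reps$KiM2_hat), 100 * median(reps$rel_error),
            100 * max(reps$rel_error)))

## identifiability profiles for the activation constants -----------------------
# residual sum of squares along one-parameter slices through the truth, on a
# noise-free GSH dose-response dataset
dr_des <- assay_design("gsh_dose_response", doses_mM = c(1, 3, 5, 7, 10, 20))
dr_ds <- generate_dataset(dr_des, truep, cv = 0, seed = 1)
slice <- function(name, values) {
  do.call(rbind, lapply(values, function(v) {
    p <- kinetic_parameters(base = truep)
    p[[name]] <- v
    f <- fit_to_dataset(dr_ds, character(0), base_params = p)
    data.frame(parameter = name, value = v, rss = f$objective)
  }))
}
prof <- rbind(slice("Vmax", truep$Vmax * c(0.5, 0.8, 0.95, 1, 1.05, 1.25, 2)),
              slice("k10", truep$k10 * c(0.5, 0.8, 0.95, 1, 1.05, 1.25, 2)))
write_result_csv(prof, "results/profile_activation.csv",
                 spec_info = list(analysis = "activation-constant profiles",
                                  design = unclass(dr_des)),
                 params = truep)
for (nm in c("Vmax", "k10")) {
  s <- prof[prof$parameter == nm, ]
  cat(sprintf("%s profile: rss at 0.8x / 1x / 1.25x truth = %.3g / %.3g / %.3g\n",
              nm, s$rss[s$value == truep[[nm]] * 0.8],
              s$rss[s$value == truep[[nm]]],
              s$rss[s$value == truep[[nm]] * 1.25]))
}
cat("Both profiles curve away from the truth on this design, but the Vmax\n",
    "profile is shallow near its minimum: with yields this far from\n",
    "saturation the dose-response constrains the product of activation and\n",
    "velocity more sharply than either factor alone.\n")
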