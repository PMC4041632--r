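#!/usr/bin/env Rscript
# Two-hour GSH dose-response of methylation yield: 1 muM iAs incubated with
# 1-20 mM GSH. Rising GSH first activates the methyltransferase and speeds
# the reductions; past the activation saturation, sequestration of iAs as
# the triglutathione conjugate takes over, so the summed MMAs+DMAs yield
# has an interior optimum.
#
# Outputs: results/gsh_dose_response.csv (6-dose grid)
#          results/gsh_dose_response_alt_grid.csv (4-dose grid)

suppressPackageStartupMessages(library(arsmet))
dir.create("results", showWarnings = FALSE)
p <- kinetic_parameters()

dr <- gsh_dose_response(params = p)
write_result_csv(dr$table, "results/gsh_dose_response.csv",
                 spec_info = list(preset = "gsh_dose_response",
                                  doses_mM = c(1, 3, 5, 7, 10, 20),
                                  horizon_h = 2),
                 params = p)
print(dr$table, row.names = FALSE, digits = 4)
cat(sprintf("Interpolated optimum of MMAs+DMAs: %.2f mM GSH\n", dr$optimum_mM))

alt <- gsh_dose_response(c(1, 5, 10, 20), params = p)
write_result_csv(alt$table, "results/gsh_dose_response_alt_grid.csv",
                 spec_info = list(preset = "gsh_dose_response",
                                  doses_mM = c(1, 5, 10, 20), horizon_h = 2),
                 params = p)
cat(sprintf("On the coarser 4-dose grid the optimum interpolates to %.2f mM.\n",
            alt$optimum_mM))
cat("Yield at 20 mM falls below the optimum: activation has saturated while\n",
    "triglutathione sequestration of iAs keeps growing with the GSH cube.\n")
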