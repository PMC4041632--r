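#!/usr/bin/env Rscript
# Methylation-flux dynamics under GSH decay: 20 mM GSH and 1 muM iAs, GSH
# half-life 2.5 h, followed for 8 h. Early on, triglutathione sequestration
# withholds part of the substrate; as GSH decays the conjugate releases it
# and the flux climbs; late, GSH falls below the activation range of the
# methyltransferase and the flux collapses — an interior peak.
#
# Output: results/flux_time_course.csv

suppressPackageStartupMessages(library(arsmet))
dir.create("results", showWarnings = FALSE)
p <- kinetic_parameters()

fx <- flux_time_course(p)
tab <- as.data.frame(fx$result)
# the peak is located on the dense 801-point grid; the table is thinned to
# 101 rows for the archive
thin <- tab[seq(1, nrow(tab), by = 8), ]
write_result_csv(thin, "results/flux_time_course.csv",
                 spec_info = list(preset = "flux_time_course",
                                  gsh_mM = 20, horizon_h = 8,
                                  equilibrated_start = TRUE),
                 params = p)

peak_flux <- max(tab$flux_total)
cat(sprintf("total methylation flux: %.3g muM/h at t=0, peak %.3g muM/h at %.2f h, %.3g muM/h at 8 h\n",
            tab$flux_total[1], peak_flux, fx$peak_time_h,
            tab$flux_total[nrow(tab)]))
cat(sprintf("first step (U*V1) carries %.1f%% of the peak flux; the second step\n",
            100 * tab$flux_v1[which.max(tab$flux_total)] / peak_flux))
cat("is throttled throughout because free MMAsIII is held as its conjugate.\n")
cat("An experiment read out near the flux peak and one read out at 8 h would\n",
    "reach opposite conclusions about the methylation rate: GSH must be\n",
    "tracked over time in assays lasting hours.\n")
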