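#!/usr/bin/env Rscript
# Calibration of the unmeasured activation/velocity constants.
#
# The literature fixes every rate constant of the model except the velocity
# scale Vmax and the activation constants (k9, k10, u_basal). Those are
# pinned here against the four semi-quantitative constraints the source
# experiments provide (see default_problem()). Because the methylation
# fluxes depend on U * Vmax only, the activation ceiling is fixed by the
# convention u_basal + k9 = 1e4 and (Vmax, k10, u_basal) are fitted.
#
# Outputs: results/calibration_result.json
#          results/fig2_horizon_sensitivity.csv

suppressPackageStartupMessages(library(arsmet))
dir.create("results", showWarnings = FALSE)

## 1. The shipped defaults against the shipped constraint set -----------------
cal <- calibrate(default_problem(seed = 20260921))
cat("Shipped defaults against the four interval constraints:\n")
print(cal)

## 2. Robustness: refit from a deliberately naive start -----------------------
# A start with a mid-range half-activation point and a much larger velocity
# violates three of the four constraints; a reduced multistart finds its way
# back to a feasible region.
naive <- kinetic_parameters(Vmax = 1e-4, k10 = 5000, u_basal = 500)
pb <- default_problem(seed = 20260921)
pb$n_starts <- 4L
pb$max_eval <- 40L
refit <- calibrate(pb, naive)
cat("\nRefit from a naive start (Vmax=1e-4, k10=5000, u_basal=500):\n")
print(refit)

jsonlite::write_json(
  list(shipped = list(fitted = as.list(cal$fitted),
                      objective = cal$objective,
                      converged = cal$converged,
                      residuals = cal$residuals),
       refit = list(start = list(Vmax = 1e-4, k10 = 5000, u_basal = 500),
                    fitted = as.list(refit$fitted),
                    objective = refit$objective,
                    converged = refit$converged,
                    n_eval = refit$n_eval)),
  "results/calibration_result.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

## 3. Sensitivity of the four-fold ratio to the sweep horizon -----------------
# The substrate-sweep assay's incubation time is not reported; the preset
# defaults to 1 h. The GSH gain of the peak DMAs yield depends on it, since
# GSH decays and the MMAsIII conjugate releases substrate over time.
p <- cal$params
sens <- do.call(rbind, lapply(c(0.5, 0.75, 1, 1.5, 2), function(h) {
  r0 <- mmas_sweep(0, seq(0, 20, by = 1), p, horizon_h = h)
  r1 <- mmas_sweep(1, seq(0, 20, by = 1), p, horizon_h = h)
  data.frame(horizon_h = h,
             peak_ratio = max(r1$total_DMAs) / max(r0$total_DMAs))
}))
cat("\nPeak-ratio sensitivity to the sweep horizon:\n")
print(sens, row.names = FALSE)
write_result_csv(sens, "results/fig2_horizon_sensitivity.csv",
                 spec_info = list(analysis = "fig2 horizon sensitivity",
                                  doses = "0-20 by 1 muM"),
                 params = p)
cat("\nThe four-fold gain is reproduced at the default 1 h horizon; shorter\n",
    "incubations overshoot it and longer ones undershoot, so the printed\n",
    "ratio constrains the assay time to roughly its stated 'about four'.\n")
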