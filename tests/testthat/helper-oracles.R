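# Shared fixtures and independent oracles used across the suite.

# dense 1-D grid-search argmax, independent of any closed form
grid_argmax <- function(f, lower, upper, step = 1e-3) {
  g <- seq(lower, upper, by = step)
  g[which.max(vapply(g, f, numeric(1)))]
}

# random admissible model state in assay-like ranges
random_state <- function() {
  model_state(
    iAs = runif(1, 0, 20), MMAsV = runif(1, 0, 20),
    MMAsIII = runif(1, 0, 20), DMAsV = runif(1, 0, 20),
    DMAsIII = runif(1, 0, 20), AsTG = runif(1, 0, 50),
    GSH = runif(1, 0, 20000), MMAsG = runif(1, 0, 50),
    DMAsG = runif(1, 0, 50)
  )
}

# coarse substrate-inhibition sweep design used by the recovery tests
recovery_design <- function() {
  assay_design("mmas_sweep", gsh_mM = 0,
               doses = c(0.5, 1, 2, 3, 5, 7, 10, 14, 20), horizon_h = 1)
}
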