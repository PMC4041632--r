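# Integration harness, dose sweeps and argmax interpolation.

test_that("experiment_spec validates its fields", {
  s <- model_state(iAs = 1)
  expect_error(experiment_spec(s, -1), "positive")
  expect_error(experiment_spec(s, 1, readout_times = c(0.5, 0.2)),
               "increasing")
  expect_error(experiment_spec(s, 1, readout_times = c(0, 2)), "within")
  expect_error(experiment_spec(s, 1, variant = "u_constant"), "u_value")
  expect_error(experiment_spec(s, 1, variant = "nope"), "arg")
  ok <- experiment_spec(s, 1, variant = "u_constant", u_value = 5000)
  expect_s3_class(ok, "experiment_spec")
})

test_that("the all-zero initial state stays identically zero", {
  spec <- experiment_spec(model_state(), 5)
  res <- run_time_course(spec, kinetic_parameters())
  expect_true(all(res$states == 0))
})

test_that("total arsenic is conserved along a methylating trajectory", {
  spec <- experiment_spec(model_state(iAs = 1, GSH = 1000), 40 / 60)
  res <- run_time_course(spec, kinetic_parameters())
  expect_true(all(abs(res$derived$total_arsenic - 1) < 1e-6))
})

test_that("arsenic-free GSH decay follows the closed-form half-life exactly", {
  p <- kinetic_parameters()
  spec <- experiment_spec(model_state(GSH = 20000), 10,
                          readout_times = c(0, 1, 2.5, 5, 10))
  res <- run_time_course(spec, p)
  expect_equal(res$states[, "GSH"], 20000 * 2^(-res$times / 2.5),
               tolerance = 1e-7)
  expect_equal(res$states[res$times == 2.5, "GSH"][[1]], 10000,
               tolerance = 1e-6)
})

test_that("with k4 = 0 the GSH pool is conserved; with k4 > 0 it decreases", {
  s <- model_state(iAs = 1, MMAsIII = 1, GSH = 5000)
  res0 <- run_time_course(experiment_spec(s, 2), kinetic_parameters(k4 = 0))
  expect_equal(res0$derived$gsh_pool, rep(5000, length(res0$times)),
               tolerance = 1e-8)
  res1 <- run_time_course(experiment_spec(s, 2), kinetic_parameters())
  expect_true(all(diff(res1$derived$gsh_pool) < 0))
})

test_that("halving the tolerances leaves readouts unchanged to 1e-6 muM", {
  p <- kinetic_parameters()
  spec <- experiment_spec(model_state(iAs = 1, GSH = 7000), 2,
                          readout_times = c(0.5, 1, 2))
  a <- run_time_course(spec, p)
  b <- run_time_course(spec, p, rtol = 0.5e-8, atol = 0.5e-10)
  arsenic <- setdiff(colnames(a$states), "GSH")
  expect_lt(max(abs(a$states[, arsenic] - b$states[, arsenic])), 1e-6)
  # GSH sits at mM scale; its convergence is relative
  expect_lt(max(abs(a$states[, "GSH"] / b$states[, "GSH"] - 1)), 1e-6)
})

test_that("the no_conjugation variant keeps all conjugates identically zero", {
  spec <- experiment_spec(model_state(iAs = 1, GSH = 10000), 2,
                          variant = "no_conjugation")
  res <- run_time_course(spec, kinetic_parameters())
  expect_true(all(res$states[, c("AsTG", "MMAsG", "DMAsG")] == 0))
})

test_that("u_constant runs pin the activation regardless of GSH", {
  p <- kinetic_parameters()
  mk <- function(g) {
    run_time_course(experiment_spec(model_state(iAs = 1, GSH = g), 0.5,
                                    readout_times = c(0, 0.5),
                                    variant = "u_constant", u_value = 5000), p)
  }
  lo <- mk(100); hi <- mk(15000)
  # at t = 0 the states differ only in GSH, so the frozen-U fluxes agree
  expect_equal(lo$derived$flux_v1[1], hi$derived$flux_v1[1])
  expect_equal(lo$derived$flux_v1[1], 5000 * v1(1, 0, p))
})

test_that("dose_sweep returns one row per dose and tags failures", {
  p <- kinetic_parameters()
  tmpl <- experiment_spec(model_state(GSH = 1000), 0.5, readout_times = 0.5)
  tab <- dose_sweep(c(0, 1, 5), "MMAsIII", tmpl, p)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$dose, c(0, 1, 5))
  expect_true(all(tab$total_DMAs >= 0))
  expect_error(dose_sweep(numeric(0), "MMAsIII", tmpl, p), "nonempty")
  expect_error(dose_sweep(1, "XXX", tmpl, p), "dose_target")
})

test_that("interpolated_argmax recovers vertices and honours boundaries", {
  # exact parabola: vertex recovered algebraically
  f <- function(x) -(x - 3.3)^2 + 7
  x <- c(1, 2.5, 6)
  expect_equal(interpolated_argmax(x, f(x)), 3.3, tolerance = 1e-12)
  # symmetric responses around the middle of an even grid
  expect_equal(interpolated_argmax(c(1, 2, 3), c(0.2, 1, 0.2)), 2)
  # strictly increasing: boundary rule
  expect_equal(interpolated_argmax(c(1, 2, 3), c(1, 2, 3)), 3)
  expect_equal(interpolated_argmax(c(1, 2), c(5, 1)), 1)
  expect_error(interpolated_argmax(1, 1), "at least 2")
  expect_error(interpolated_argmax(c(2, 1), c(1, 2)), "increasing")
})

test_that("forward simulation is bitwise reproducible", {
  p <- kinetic_parameters()
  a <- gsh_dose_response(c(1, 7), p)
  b <- gsh_dose_response(c(1, 7), p)
  expect_identical(a, b)
})
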