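# Interval calibration and least-squares fitting.

test_that("the shipped problem has the four printed constraints and round-trips", {
  pb <- default_problem(seed = 7)
  expect_gte(length(pb$constraints), 4)
  expect_setequal(names(pb$free), c("Vmax", "k10", "u_basal"))
  path <- withr::local_tempfile(fileext = ".json")
  write_problem(pb, path)
  pb2 <- read_problem(path)
  expect_equal(pb2, pb)
})

test_that("problem construction validates bounds and constraints", {
  expect_error(calibration_problem(list(Vmax = c(2, 1)),
                                   list(constraint("u_activation_value", 0, 1))),
               "bounds")
  expect_error(calibration_problem(list(Vmax = c(1e-6, 1e-1)), list()),
               "constraint")
  expect_error(constraint("nope", 0, 1), "unknown summary")
  expect_error(constraint("u_activation_value", 2, 1), "lower <= upper")
})

test_that("every shipped constraint evaluates cleanly at the default parameters", {
  pb <- default_problem()
  vals <- arsmet:::.constraint_values(kinetic_parameters(), pb$constraints)
  expect_true(all(is.finite(vals)))
  expect_length(vals, length(pb$constraints))
})

test_that("a start satisfying the constraints is a fixed point of calibrate", {
  pb <- calibration_problem(
    free = list(k10 = c(100, 20000)),
    constraints = list(constraint("u_activation_value", 0, 1e5,
                                  opts = list(gsh = 1000))),
    seed = 1)
  p0 <- kinetic_parameters()
  res <- calibrate(pb, p0)
  expect_equal(res$fitted[["k10"]], p0$k10)
  expect_identical(res$objective, 0)
  expect_true(res$converged)
  expect_equal(res$n_eval, 1L)
})

test_that("calibrate improves an infeasible start and is seed-deterministic", {
  # demand a half-activation point such that U(2000) sits in a narrow band,
  # infeasible at the default k10
  pb <- calibration_problem(
    free = list(k10 = c(100, 20000)),
    constraints = list(constraint("u_activation_value", 200, 210,
                                  opts = list(gsh = 2000))),
    seed = 3, n_starts = 4, max_eval = 80)
  p0 <- kinetic_parameters(u_basal = 0)
  base_obj <- arsmet:::.objective(p0, pb$constraints)$objective
  expect_gt(base_obj, 0)
  res1 <- calibrate(pb, p0)
  res2 <- calibrate(pb, p0)
  expect_lte(res1$objective, base_obj)
  expect_true(res1$converged)
  expect_identical(res1$fitted, res2$fitted)
  expect_identical(res1$objective, res2$objective)
})

test_that("the objective is invariant under constraint reordering", {
  p <- kinetic_parameters()
  cons <- list(constraint("u_activation_value", 0, 50, opts = list(gsh = 500)),
               constraint("u_activation_value", 1, 2, opts = list(gsh = 3000)))
  o1 <- arsmet:::.objective(p, cons)$objective
  o2 <- arsmet:::.objective(p, rev(cons))$objective
  expect_identical(o1, o2)
})

test_that("calibrate rejects a start outside the bounds", {
  pb <- calibration_problem(
    free = list(k10 = c(100, 200)),
    constraints = list(constraint("u_activation_value", 0, 1)), seed = 1)
  expect_error(calibrate(pb, kinetic_parameters()), "bounds")
})

test_that("fitting with zero free parameters returns the inputs and their residual", {
  ds <- generate_dataset(recovery_design(), kinetic_parameters(), cv = 0.1,
                         seed = 5)
  fit <- fit_to_dataset(ds, character(0))
  expect_length(fit$fitted, 0)
  expect_identical(unclass(fit$params), unclass(kinetic_parameters()))
  expect_gt(fit$objective, 0)
})

test_that("a noise-free dataset returns its generating parameter", {
  truep <- kinetic_parameters()
  ds <- generate_dataset(recovery_design(), truep, cv = 0, seed = 1)
  fit <- fit_to_dataset(ds, "KiM2", bounds = list(KiM2 = c(1, 30)), seed = 1)
  expect_equal(fit$fitted[["KiM2"]], truep$KiM2, tolerance = 1e-2)
  expect_error(fit_to_dataset(ds, "KiM2"), "bounds")
  expect_error(fit_to_dataset(ds, "nope", bounds = list(nope = c(0, 1))),
               "unknown free")
})
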