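# Parameters, state containers and the kinetic laws.

test_that("default parameters carry the literature rate constants exactly", {
  p <- kinetic_parameters()
  expect_identical(p$k1, 1e-11)
  expect_identical(p$k_1, 375)
  expect_identical(p$k2, 1e-5)
  expect_identical(p$k_2, 0.25)
  expect_identical(p$k3, 1e-3)
  expect_identical(p$k_3, 1e-3)
  expect_identical(p$k4, log(2) / 2.5)
  expect_identical(p$k5, 100)
  expect_identical(p$k6, 0.1)
  expect_identical(p$k7, 5)
  expect_identical(p$k8, 0.1)
  expect_identical(p$Km, 4.6)
  expect_identical(p$KiA, 1.26)
  expect_identical(p$KiM, 40)
  expect_identical(p$KiA2, 40)
  expect_identical(p$KiM2, 6)
})

test_that("parameter validation rejects bad values and unknown names", {
  expect_error(kinetic_parameters(Km = -1), "strictly positive|nonnegative")
  expect_error(kinetic_parameters(k10 = 0), "strictly positive")
  expect_error(kinetic_parameters(k5 = -3), "nonnegative")
  expect_error(kinetic_parameters(bogus = 1), "unknown parameter")
  expect_error(kinetic_parameters(Km = NA_real_), "finite")
})

test_that("overriding u_basal preserves the activation-scale convention", {
  p <- kinetic_parameters(u_basal = 250)
  expect_equal(p$u_basal + p$k9, 1e4)
})

test_that("model_state builds a canonical nonnegative vector", {
  s <- model_state(iAs = 1, GSH = 1000)
  expect_named(s, c("iAs", "MMAsV", "MMAsIII", "DMAsV", "DMAsIII",
                    "AsTG", "GSH", "MMAsG", "DMAsG"))
  expect_equal(total_arsenic(s), 1)
  expect_equal(gsh_pool(s), 1000)
  expect_error(model_state(iAs = -1), "nonnegative")
  expect_error(model_state(foo = 1), "unknown state")
})

test_that("conjugate stoichiometry enters the GSH pool as 3, 2, 1", {
  s <- model_state(AsTG = 2, MMAsG = 3, DMAsG = 5, GSH = 10)
  expect_equal(gsh_pool(s), 10 + 6 + 6 + 5)
  expect_equal(total_arsenic(s), 10)
})

test_that("u_activation has basal floor, Hill half-point and saturation ceiling", {
  p <- kinetic_parameters(u_basal = 0)
  expect_equal(u_activation(0, p), 0)
  expect_equal(u_activation(p$k10, p), p$k9 / 2)
  expect_equal(u_activation(1e12, p), p$k9, tolerance = 1e-6)
  pb <- kinetic_parameters(u_basal = 7, k9 = 100)
  expect_equal(u_activation(0, pb), 7)
  expect_lt(u_activation(1e12, pb), 107 + 1e-9)
  expect_error(u_activation(-1, p), "nonnegative")
})

test_that("u_activation is monotone nondecreasing in GSH", {
  p <- kinetic_parameters()
  set.seed(11)
  for (i in 1:50) {
    g <- sort(runif(2, 0, 30000))
    expect_lte(u_activation(g[1], p), u_activation(g[2], p))
  }
})

test_that("v1 vanishes iff substrate is absent and is relieved by weaker product inhibition", {
  p <- kinetic_parameters()
  expect_equal(v1(0, 5, p), 0)
  expect_gt(v1(1, 0, p), 0)
  expect_gt(v1(2, 3, kinetic_parameters(KiM = 80)), v1(2, 3, p))
  expect_gt(v1(2, 0, p), v1(2, 5, p))  # strictly decreasing in MMAsV
  expect_error(v1(-1, 0, p), "nonnegative")
  expect_error(v1(1, -2, p), "nonnegative")
})

test_that("v1's optimum over iAs equals sqrt(Km * KiA) for random parameter draws", {
  set.seed(42)
  for (i in 1:12) {
    p <- kinetic_parameters(Km = runif(1, 0.5, 20), KiA = runif(1, 0.2, 50))
    closed <- sqrt(p$Km * p$KiA)
    grid <- grid_argmax(function(s) v1(s, 0, p), 0.01, 2 * closed + 10,
                        step = 5e-3)
    expect_equal(grid, closed, tolerance = 6e-3)
  }
})

test_that("v2 is non-monotone with an interior optimum near 3.7 muM", {
  p <- kinetic_parameters()
  expect_equal(v2(0, 0, p), 0)
  opt <- grid_argmax(function(s) v2(s, 0, p), 0.01, 25, step = 5e-4)
  expect_equal(opt, 3.7, tolerance = 0.01)
  expect_gt(v2(opt, 0, p), v2(20, 0, p))
  expect_gt(v2(opt, 0, p), v2(0.5, 0, p))
  expect_error(v2(-1, 0, p), "nonnegative")
})

test_that("v2 inhibition by iAs halves the velocity at iAs = KiA2", {
  p <- kinetic_parameters()
  expect_equal(v2(5, 40, p), v2(5, 0, p) / 2)
})

test_that("reduction rates are affine in GSH with the printed intercepts", {
  p <- kinetic_parameters()
  expect_equal(reduction_rate_mmas(0, p), 100)
  expect_equal(reduction_rate_mmas(1000, p), 200)
  expect_equal(reduction_rate_dmas(0, p), 5)
  expect_equal(reduction_rate_dmas(1000, p), 105)
  set.seed(3)
  for (g in runif(5, 0, 2e4)) {
    expect_equal(reduction_rate_mmas(2 * g, p) - reduction_rate_mmas(g, p),
                 p$k6 * g)
    expect_gte(reduction_rate_dmas(g, p), p$k7)
  }
  expect_error(reduction_rate_mmas(-1, p), "nonnegative")
})

test_that("the zero state is an equilibrium of the ODE right-hand side", {
  p <- kinetic_parameters()
  d <- ode_rhs(model_state(), p)
  expect_true(all(d == 0))
})

test_that("arsenic atoms and GSH equivalents are conserved by the equations", {
  p <- kinetic_parameters()
  set.seed(7)
  for (i in 1:100) {
    s <- random_state()
    d <- ode_rhs(s, p)
    scale <- max(1, max(abs(d)))
    expect_lt(abs(total_arsenic(d)), 1e-8 * scale)
    expect_lt(abs(gsh_pool(d) + p$k4 * s[["GSH"]]), 1e-8 * scale)
  }
})

test_that("ode_rhs rejects negative states and negative activation overrides", {
  p <- kinetic_parameters()
  s <- model_state(iAs = 1)
  s[["iAs"]] <- -1
  expect_error(ode_rhs(s, p), "nonnegative")
  expect_error(ode_rhs(model_state(iAs = 1), p, u = -5), "nonnegative")
})

test_that("equilibrate_conjugates preserves pool totals and GSH equivalents", {
  p <- kinetic_parameters()
  s <- model_state(iAs = 1, MMAsIII = 2, DMAsIII = 0.5, GSH = 20000)
  e <- equilibrate_conjugates(s, p)
  expect_equal(total_arsenic(e), total_arsenic(s))
  expect_equal(gsh_pool(e), gsh_pool(s), tolerance = 1e-10)
  expect_equal(e[["iAs"]] + e[["AsTG"]], 1)
  # detailed balance of each conjugation at the reported free GSH
  g <- e[["GSH"]]
  expect_equal(p$k1 * g^3 * e[["iAs"]], p$k_1 * e[["AsTG"]], tolerance = 1e-6)
  expect_equal(p$k2 * g^2 * e[["MMAsIII"]], p$k_2 * e[["MMAsG"]],
               tolerance = 1e-6)
})
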