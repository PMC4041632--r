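# Calibration of the unmeasured activation/velocity constants against
# interval constraints, and a general least-squares fitter for parameter
# recovery from (synthetic) assay datasets.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Registry of scalar summaries a constraint can target. Each entry is a
# function(params, opts) -> scalar. Declarative (name + opts) so problems
# serialize to JSON and round-trip exactly.
.summary_registry <- function() {
  list(
    fig2_peak_ratio = function(params, opts) {
      doses <- opts$doses %||% seq(0, 20, by = 2)
      h <- opts$horizon_h %||% 1
      r0 <- mmas_sweep(0, doses, params, horizon_h = h)
      r1 <- mmas_sweep(1, doses, params, horizon_h = h)
      max(r1$total_DMAs) / max(r0$total_DMAs)
    },
    gsh_optimum_mM = function(params, opts) {
      doses <- opts$doses_mM %||% c(1, 3, 5, 7, 10, 20)
      gsh_dose_response(doses, params)$optimum_mM
    },
    flux_peak_time_h = function(params, opts) {
      flux_time_course(params, n_times = opts$n_times %||% 161L)$peak_time_h
    },
    basal_methylation_ratio = function(params, opts) {
      yield <- function(g) {
        d <- time_course(g, params, n_times = 9L)$derived
        n <- nrow(d)
        d$total_MMAs[n] + d$total_DMAs[n]
      }
      yield(0) / yield(1)
    },
    # cheap summary used in unit tests of the optimizer machinery
    u_activation_value = function(params, opts) {
      u_activation(opts$gsh %||% 1000, params)
    }
  )
}

#' Define an interval constraint on a model summary
#'
#' @param summary name of a registered scalar summary (one of
#'   `fig2_peak_ratio`, `gsh_optimum_mM`, `flux_peak_time_h`,
#'   `basal_methylation_ratio`, `u_activation_value`).
#' @param lower,upper target interval for the summary (hinge penalty: zero
#'   inside, squared relative distance outside).
#' @param weight nonnegative weight in the objective.
#' @param opts list of plain options forwarded to the summary function.
#' @return a constraint specification (list).
#' @export
constraint <- function(summary, lower, upper, weight = 1, opts = list()) {
  if (!summary %in% names(.summary_registry())) {
    stop("unknown summary '", summary, "'", call. = FALSE)
  }
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    stop("need finite lower <= upper", call. = FALSE)
  }
  if (weight < 0) stop("weight must be nonnegative", call. = FALSE)
  list(summary = summary, lower = lower, upper = upper,
       weight = weight, opts = opts)
}

#' Define a calibration problem
#'
#' @param free named list of length-2 numeric bounds for each free
#'   parameter, e.g. `list(Vmax = c(1e-6, 1e-1))`. Bounds must be finite,
#'   positive upper, and `lower < upper`. If `u_basal` is free, `k9` is tied
#'   to it by the activation-scale convention `u_basal + k9 = 1e4`.
#' @param constraints nonempty list of [constraint()] specifications.
#' @param seed integer seed for the multistart design.
#' @param n_starts number of Latin-hypercube starts (the supplied starting
#'   parameters are always evaluated first).
#' @param max_eval objective-evaluation budget per start.
#' @return an object of class `calibration_problem`.
#' @export
calibration_problem <- function(free, constraints, seed = 1L,
                                n_starts = 16L, max_eval = 60L) {
  if (!length(free) || is.null(names(free))) {
    stop("free must be a named list of bounds", call. = FALSE)
  }
  unknown <- setdiff(names(free), .param_names)
  if (length(unknown)) {
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] < 0 || b[2] <= 0 ||
        b[1] >= b[2]) {
      stop("bounds for ", nm, " must be finite with 0 <= lower < upper",
           call. = FALSE)
    }
  }
  if (!length(constraints)) stop("need at least one constraint", call. = FALSE)
  structure(list(free = lapply(free, as.numeric), constraints = constraints,
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 max_eval = as.integer(max_eval)),
            class = "calibration_problem")
}

#' The shipped calibration problem
#'
#' Encodes the four semi-quantitative constraints the source experiments
#' pin down, as equally weighted interval targets:
#' the ~4-fold gain of peak total DMAs under 1 mM GSH in the
#' substrate-inhibition sweep (interval `[3, 5]`); the interior optimum of
#' 2-hour methylation yield between 5 and 10 mM GSH; the 4-5 h peak time of
#' the total methylation flux under decaying 20 mM GSH; and a strictly
#' positive but sub-1-mM-GSH methylation yield at 0 mM GSH in the 40-minute
#' time course (yield ratio in `[0.001, 0.95]`). Free parameters: `Vmax`,
#' `k10`, `u_basal` (with `k9 = 1e4 - u_basal`).
#'
#' @param seed integer seed.
#' @return a [calibration_problem()].
#' @export
default_problem <- function(seed = 1L) {
  calibration_problem(
    free = list(Vmax = c(1e-6, 1e-1),
                k10 = c(100, 20000),
                u_basal = c(0, 5000)),
    constraints = list(
      constraint("fig2_peak_ratio", 3, 5),
      constraint("gsh_optimum_mM", 5, 10),
      constraint("flux_peak_time_h", 4, 5),
      constraint("basal_methylation_ratio", 0.001, 0.95)
    ),
    seed = seed
  )
}

# Apply free-parameter values (named numeric) on top of base parameters,
# honouring the activation-scale convention.
.apply_free <- function(base, values) {
  args <- as.list(values)
  args$base <- base
  do.call(kinetic_parameters, args)
}

.constraint_values <- function(params, constraints) {
  reg <- .summary_registry()
  vapply(constraints, function(cn) reg[[cn$summary]](params, cn$opts),
         numeric(1))
}

.hinge_penalty <- function(value, lower, upper) {
  scale <- max(abs(lower), abs(upper), 1e-12)
  if (value < lower) ((lower - value) / scale)^2
  else if (value > upper) ((value - upper) / scale)^2
  else 0
}

.objective <- function(params, constraints) {
  vals <- .constraint_values(params, constraints)
  pen <- mapply(function(v, cn) cn$weight * .hinge_penalty(v, cn$lower, cn$upper),
                vals, constraints)
  list(objective = sum(pen), values = vals, penalties = as.numeric(pen))
}

.residual_table <- function(constraints, vals, pens) {
  data.frame(summary = vapply(constraints, `[[`, "", "summary"),
             value = vals,
             lower = vapply(constraints, `[[`, numeric(1), "lower"),
             upper = vapply(constraints, `[[`, numeric(1), "upper"),
             weight = vapply(constraints, `[[`, numeric(1), "weight"),
             penalty = pens)
}

# map unconstrained coords to bounded parameter values; log-interpolate when
# the bound ratio is large (scale parameters), linear otherwise
.decode <- function(x, bounds) {
  mapply(function(xi, b) {
    s <- stats::plogis(xi)
    if (b[1] > 0 && b[2] / b[1] > 100) exp(log(b[1]) + s * (log(b[2]) - log(b[1])))
    else b[1] + s * (b[2] - b[1])
  }, x, bounds)
}

.encode <- function(v, bounds) {
  mapply(function(vi, b) {
    s <- if (b[1] > 0 && b[2] / b[1] > 100) {
      (log(vi) - log(b[1])) / (log(b[2]) - log(b[1]))
    } else {
      (vi - b[1]) / (b[2] - b[1])
    }
    stats::qlogis(min(max(s, 1e-6), 1 - 1e-6))
  }, v, bounds)
}

#' Calibrate free parameters against interval constraints
#'
#' Minimizes the weighted hinge-penalty objective of `problem` over its free
#' parameters, starting from `params0`. If `params0` already satisfies every
#' constraint (objective exactly zero) it is returned unchanged. Otherwise a
#' seeded Latin-hypercube multistart of Nelder-Mead searches (on smoothly
#' bounded coordinates) is run; the best start wins, ties broken by lowest
#' objective then lowest start index. Deterministic given the problem seed.
#'
#' @param problem a [calibration_problem()].
#' @param params0 starting [kinetic_parameters()].
#' @return an object of class `calibration_result`: `fitted` (named values of
#'   the free parameters), `params` (full parameter set), `residuals` (per
#'   constraint: value, interval, penalty), `objective`, `converged` (all
#'   constraints satisfied), `n_eval`, `seed`.
#' @export
calibrate <- function(problem, params0 = kinetic_parameters()) {
  if (!inherits(problem, "calibration_problem")) {
    stop("problem must be a calibration_problem", call. = FALSE)
  }
  validate_parameters(params0)
  free <- problem$free
  for (nm in names(free)) {
    v <- params0[[nm]]
    if (v < free[[nm]][1] || v > free[[nm]][2]) {
      stop("params0$", nm, " outside its bounds", call. = FALSE)
    }
  }
  n_eval <- 0L
  evalf <- function(values) {
    n_eval <<- n_eval + 1L
    .objective(.apply_free(params0, values), problem$constraints)
  }
  start_vals <- vapply(names(free), function(nm) params0[[nm]], numeric(1))
  ob0 <- evalf(start_vals)
  if (ob0$objective == 0) {
    return(structure(list(
      fitted = start_vals, params = .apply_free(params0, start_vals),
      residuals = .residual_table(problem$constraints, ob0$values, ob0$penalties),
      objective = 0, converged = TRUE, n_eval = n_eval,
      seed = problem$seed), class = "calibration_result"))
  }
  set.seed(problem$seed)
  d <- length(free)
  design <- lhs::randomLHS(max(problem$n_starts - 1L, 0L), d)
  starts <- list(start_vals)
  if (nrow(design) > 0) {
    for (i in seq_len(nrow(design))) {
      starts[[i + 1L]] <- vapply(seq_len(d), function(j) {
        b <- free[[j]]
        if (b[1] > 0 && b[2] / b[1] > 100) {
          exp(log(b[1]) + design[i, j] * (log(b[2]) - log(b[1])))
        } else {
          b[1] + design[i, j] * (b[2] - b[1])
        }
      }, numeric(1))
    }
  }
  best <- NULL
  for (i in seq_along(starts)) {
    sv <- stats::setNames(pmin(pmax(starts[[i]],
                                    vapply(free, `[`, numeric(1), 1)),
                               vapply(free, `[`, numeric(1), 2)),
                          names(free))
    fn <- function(x) {
      vals <- stats::setNames(.decode(x, free), names(free))
      evalf(vals)$objective
    }
    opt <- if (d == 1L) {
      stats::optim(.encode(sv, free), fn, method = "Brent",
                   lower = stats::qlogis(1e-6), upper = stats::qlogis(1 - 1e-6),
                   control = list(maxit = problem$max_eval))
    } else {
      stats::optim(.encode(sv, free), fn, method = "Nelder-Mead",
                   control = list(maxit = problem$max_eval, reltol = 1e-8))
    }
    vals <- stats::setNames(.decode(opt$par, free), names(free))
    cand <- list(values = vals, objective = opt$value, start = i)
    if (is.null(best) || cand$objective < best$objective - 1e-15) best <- cand
    if (best$objective == 0) break
  }
  fitted <- best$values
  pfit <- .apply_free(params0, fitted)
  obf <- .objective(pfit, problem$constraints)
  structure(list(
    fitted = fitted, params = pfit,
    residuals = .residual_table(problem$constraints, obf$values, obf$penalties),
    objective = obf$objective, converged = obf$objective == 0,
    n_eval = n_eval, seed = problem$seed), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result (objective ", format(x$objective),
      if (x$converged) ", all constraints satisfied" else ", NOT converged",
      "; ", x$n_eval, " evaluations)\n", sep = "")
  cat("Fitted:\n")
  print(x$fitted)
  print(x$residuals)
  invisible(x)
}

#' Least-squares fit of free parameters to an assay dataset
#'
#' Minimizes the sum of squared standardized residuals between the model's
#' noise-free readouts for the dataset's design and the observed readouts.
#' Residuals are standardized by the proportional-noise scale
#' `cv * max(obs, floor)` when the dataset's CV is positive, and unstandardized
#' otherwise. One free parameter is fitted by golden-section search
#' ([stats::optimize()]); several by a seeded Latin-hypercube multistart of
#' Nelder-Mead searches. Deterministic given `seed`.
#'
#' @param dataset a [generate_dataset()] object (or compatible list with
#'   `design`, `observations`, `readouts`, `cv`, `true_params`).
#' @param free character vector of parameter names to fit (may be empty:
#'   the base parameters and their residual are returned unchanged).
#' @param bounds named list of length-2 bounds, one per free parameter.
#' @param seed integer seed for the multistart design.
#' @param base_params parameters for all non-free constants; defaults to the
#'   dataset's true parameters (parameter-recovery convention).
#' @param n_starts multistart size for multi-parameter fits.
#' @param tol optimizer tolerance on the free parameters.
#' @return a `calibration_result` with fields `fitted`, `params`,
#'   `objective` (residual sum of squares), `converged`, `n_eval`, `seed`.
#' @export
fit_to_dataset <- function(dataset, free, bounds = NULL, seed = 1L,
                           base_params = NULL, n_starts = 4L, tol = 1e-4) {
  base_params <- base_params %||% dataset$true_params
  validate_parameters(base_params)
  obs <- as.matrix(dataset$observations[, dataset$readouts, drop = FALSE])
  scale <- if (!is.null(dataset$cv) && dataset$cv > 0) {
    dataset$cv * pmax(obs, 0.05 * max(obs))
  } else {
    matrix(1, nrow(obs), ncol(obs))
  }
  n_eval <- 0L
  rss <- function(params) {
    n_eval <<- n_eval + 1L
    sim <- as.matrix(simulate_design(dataset$design, params)[, dataset$readouts,
                                                             drop = FALSE])
    sum(((sim - obs) / scale)^2)
  }
  finish <- function(fitted) {
    pfit <- if (length(fitted)) .apply_free(base_params, fitted) else base_params
    obj <- rss(pfit)
    structure(list(fitted = fitted, params = pfit, residuals = NULL,
                   objective = obj, converged = TRUE, n_eval = n_eval,
                   seed = as.integer(seed)),
              class = "calibration_result")
  }
  if (!length(free)) return(finish(stats::setNames(numeric(0), character(0))))
  unknown <- setdiff(free, .param_names)
  if (length(unknown)) {
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(bounds) || !all(free %in% names(bounds))) {
    stop("bounds must be supplied for every free parameter", call. = FALSE)
  }
  bounds <- bounds[free]
  if (length(free) == 1L) {
    b <- bounds[[1]]
    opt <- stats::optimize(function(v) {
      rss(.apply_free(base_params, stats::setNames(v, free)))
    }, interval = b, tol = tol)
    return(finish(stats::setNames(opt$minimum, free)))
  }
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, length(free))
  best <- NULL
  for (i in seq_len(n_starts)) {
    sv <- vapply(seq_along(free), function(j) {
      b <- bounds[[j]]
      if (b[1] > 0 && b[2] / b[1] > 100) {
        exp(log(b[1]) + design[i, j] * (log(b[2]) - log(b[1])))
      } else {
        b[1] + design[i, j] * (b[2] - b[1])
      }
    }, numeric(1))
    fn <- function(x) {
      vals <- stats::setNames(.decode(x, bounds), free)
      rss(.apply_free(base_params, vals))
    }
    opt <- stats::optim(.encode(stats::setNames(sv, free), bounds), fn,
                        method = "Nelder-Mead",
                        control = list(maxit = 200L, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  finish(stats::setNames(.decode(best$par, bounds), free))
}

#' Serialize / parse a calibration problem
#'
#' Problems are declarative (summary names, intervals, options, bounds,
#' seed), so they serialize to JSON and parse back to an identical object.
#'
#' @param problem a [calibration_problem()].
#' @param path file path.
#' @return `write_problem` returns `path` invisibly; `read_problem` the
#'   parsed `calibration_problem`.
#' @export
write_problem <- function(problem, path) {
  jsonlite::write_json(unclass(problem), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_problem
#' @export
read_problem <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  constraints <- lapply(raw$constraints, function(cn) {
    constraint(cn$summary, cn$lower, cn$upper, cn$weight,
               opts = lapply(cn$opts, unlist))
  })
  calibration_problem(free = raw$free, constraints = constraints,
                      seed = raw$seed, n_starts = raw$n_starts,
                      max_eval = raw$max_eval)
}
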