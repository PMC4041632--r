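# Simulation engine: experiment specifications, stiff integration with
# conservation-aware post-processing, dose sweeps and argmax extraction.

.variants <- c("full", "u_constant", "no_conjugation")

#' Specify a simulation experiment
#'
#' Bundles an initial state, a horizon, readout times and a model variant.
#' Variants: `"full"` (default), `"u_constant"` (the activation factor is
#' frozen at `u_value` instead of following GSH), and `"no_conjugation"`
#' (all three conjugation reactions removed, `k1 = k2 = k3 = 0`).
#'
#' @param initial_state named state vector from [model_state()], muM.
#' @param horizon simulation horizon in hours (> 0).
#' @param readout_times times (hours) at which the trajectory is reported;
#'   must lie in `[0, horizon]` and be strictly increasing. Default: 101
#'   evenly spaced points.
#' @param variant one of `"full"`, `"u_constant"`, `"no_conjugation"`.
#' @param u_value fixed activation factor (required if `variant =
#'   "u_constant"`; nonnegative).
#' @param label free-text label carried into output sidecars.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(initial_state, horizon,
                            readout_times = NULL,
                            variant = "full", u_value = NULL,
                            label = "") {
  initial_state <- validate_state(initial_state)
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0) {
    stop("horizon must be a positive scalar (hours)", call. = FALSE)
  }
  if (is.null(readout_times)) readout_times <- seq(0, horizon, length.out = 101L)
  if (any(!is.finite(readout_times)) || any(readout_times < 0) ||
      any(readout_times > horizon + 1e-12)) {
    stop("readout_times must lie within [0, horizon]", call. = FALSE)
  }
  if (is.unsorted(readout_times, strictly = TRUE)) {
    stop("readout_times must be strictly increasing", call. = FALSE)
  }
  variant <- match.arg(variant, .variants)
  if (variant == "u_constant") {
    if (is.null(u_value) || !is.numeric(u_value) || length(u_value) != 1L ||
        !is.finite(u_value) || u_value < 0) {
      stop("variant 'u_constant' requires a nonnegative scalar u_value",
           call. = FALSE)
    }
  } else {
    u_value <- NULL
  }
  structure(list(initial_state = initial_state, horizon = horizon,
                 readout_times = as.numeric(readout_times),
                 variant = variant, u_value = u_value, label = label),
            class = "experiment_spec")
}

# Effective parameters and activation closure for a variant.
.variant_setup <- function(spec, params) {
  p <- params
  if (spec$variant == "no_conjugation") {
    p$k1 <- 0; p$k2 <- 0; p$k3 <- 0
  }
  ufun <- if (spec$variant == "u_constant") {
    force(spec)
    function(g) spec$u_value
  } else {
    function(g) u_activation(g, p)
  }
  list(params = p, ufun = ufun)
}

#' Integrate an experiment
#'
#' Runs the model over the horizon of `spec` with a stiff-capable adaptive
#' integrator (`deSolve::lsoda`, relative tolerance `1e-8`, absolute
#' tolerance `1e-10` muM by default). Readout times are evaluated on the
#' integrator's dense output. Undershoots more negative than `-1e-9` muM are
#' an error; smaller ones are clamped to zero.
#'
#' @param spec an [experiment_spec()].
#' @param params a [kinetic_parameters()] object.
#' @param rtol,atol integration tolerances.
#' @return an object of class `time_course_result`: list with `times` (hr),
#'   `states` (matrix, one row per readout time, nine state columns) and
#'   `derived` (data frame of conjugate-blind readouts and methylation
#'   fluxes: `total_MMAs = MMAsIII + MMAsV + MMAsG`, `trivalent_MMAs =
#'   MMAsIII + MMAsG`, `total_DMAs = DMAsIII + DMAsV + DMAsG`,
#'   `trivalent_DMAs = DMAsIII + DMAsG`, `iAs_like = iAs + AsTG`,
#'   `total_arsenic`, `gsh_pool`, `flux_v1 = U*V1`, `flux_v2 = U*V2`,
#'   `flux_total`), plus the spec and tolerances.
#' @export
run_time_course <- function(spec, params, rtol = 1e-8, atol = 1e-10) {
  if (!inherits(spec, "experiment_spec")) {
    stop("spec must be an experiment_spec", call. = FALSE)
  }
  validate_parameters(params)
  vs <- .variant_setup(spec, params)
  p <- vs$params
  ufun <- vs$ufun
  deriv <- function(t, y, parms) {
    y[y < 0] <- 0
    list(.rhs_kernel(y, p, ufun(y[[7L]])))
  }
  times <- spec$readout_times
  prepend0 <- times[1] > 0
  if (prepend0) times <- c(0, times)
  out <- deSolve::ode(y = spec$initial_state, times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000L)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("integrator failed (istate = ", diagn[1], ") for experiment '",
         spec$label, "'", call. = FALSE)
  }
  if (nrow(out) < length(times)) {
    stop("integrator returned a truncated trajectory for experiment '",
         spec$label, "'", call. = FALSE)
  }
  if (prepend0) out <- out[-1L, , drop = FALSE]
  states <- out[, .state_names, drop = FALSE]
  if (any(states < -1e-9)) {
    stop("integration produced a state below -1e-9 muM; tighten tolerances",
         call. = FALSE)
  }
  states[states < 0] <- 0
  if (spec$variant == "no_conjugation") {
    # without forward conjugation an initially absent conjugate has no
    # source, so its exact solution is identically zero
    for (col in c("AsTG", "MMAsG", "DMAsG")) {
      if (spec$initial_state[[col]] == 0) states[, col] <- 0
    }
  }
  tt <- out[, "time"]
  u <- vapply(states[, "GSH"], ufun, numeric(1))
  fv1 <- u * v1(states[, "iAs"], states[, "MMAsV"], p)
  fv2 <- u * v2(states[, "MMAsIII"], states[, "iAs"], p)
  derived <- data.frame(
    total_MMAs = states[, "MMAsIII"] + states[, "MMAsV"] + states[, "MMAsG"],
    trivalent_MMAs = states[, "MMAsIII"] + states[, "MMAsG"],
    total_DMAs = states[, "DMAsIII"] + states[, "DMAsV"] + states[, "DMAsG"],
    trivalent_DMAs = states[, "DMAsIII"] + states[, "DMAsG"],
    iAs_like = states[, "iAs"] + states[, "AsTG"],
    total_arsenic = total_arsenic(states),
    gsh_pool = gsh_pool(states),
    flux_v1 = fv1, flux_v2 = fv2, flux_total = fv1 + fv2
  )
  structure(list(times = tt, states = states, derived = derived,
                 spec = spec, rtol = rtol, atol = atol),
            class = "time_course_result")
}

#' @export
as.data.frame.time_course_result <- function(x, ...) {
  data.frame(time_h = x$times, as.data.frame(x$states), x$derived,
             check.names = FALSE)
}

#' @export
print.time_course_result <- function(x, ...) {
  cat("Time course '", x$spec$label, "' (variant ", x$spec$variant, "): ",
      length(x$times), " readouts over ", x$spec$horizon, " h\n", sep = "")
  cat("  final total arsenic: ",
      format(x$derived$total_arsenic[length(x$times)]), " muM\n", sep = "")
  invisible(x)
}

#' Sweep a dose over an initial-state component
#'
#' Runs one [run_time_course()] per dose, setting `dose_target` of the
#' template's initial state to the dose, and collects the end-of-horizon
#' states and derived readouts in a data frame (one row per dose, dose
#' first). Deterministic given its inputs.
#'
#' @param doses nonnegative doses, muM.
#' @param dose_target name of the initial-state component receiving the dose
#'   (e.g. `"GSH"` or `"MMAsIII"`).
#' @param spec_template an [experiment_spec()] providing everything but the
#'   dosed component.
#' @param params a [kinetic_parameters()] object.
#' @param rtol,atol integration tolerances.
#' @return data frame with columns `dose`, the nine final states and the
#'   derived readouts at the horizon.
#' @export
dose_sweep <- function(doses, dose_target, spec_template, params,
                       rtol = 1e-8, atol = 1e-10) {
  if (!length(doses) || any(!is.finite(doses)) || any(doses < 0)) {
    stop("doses must be a nonempty nonnegative vector", call. = FALSE)
  }
  if (!dose_target %in% .state_names) {
    stop("dose_target must be one of: ", paste(.state_names, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(doses, function(d) {
    st <- spec_template$initial_state
    st[[dose_target]] <- d
    sp <- experiment_spec(st, spec_template$horizon,
                          readout_times = spec_template$horizon,
                          variant = spec_template$variant,
                          u_value = spec_template$u_value,
                          label = sprintf("%s dose=%g", spec_template$label, d))
    res <- tryCatch(run_time_course(sp, params, rtol = rtol, atol = atol),
                    error = function(e) {
                      stop("sweep failed at dose ", d, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    n <- length(res$times)
    data.frame(dose = d, as.data.frame(res$states)[n, , drop = FALSE],
               res$derived[n, , drop = FALSE], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Interpolated location of a discrete maximum
#'
#' Returns the abscissa of the maximum of `responses` over `doses`, refined
#' by a quadratic through the discrete maximum and its two neighbours. A
#' maximum at either boundary of the grid is returned as the boundary value.
#' If the fitted quadratic is degenerate (collinear points) the grid maximum
#' is returned unrefined.
#'
#' @param doses strictly increasing abscissae (length >= 2).
#' @param responses responses, same length.
#' @return interpolated abscissa of the maximum.
#' @export
interpolated_argmax <- function(doses, responses) {
  if (length(doses) < 2L || length(doses) != length(responses)) {
    stop("need at least 2 points and equal lengths", call. = FALSE)
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  i <- which.max(responses)
  n <- length(doses)
  if (i == 1L || i == n) return(doses[i])
  x <- doses[(i - 1L):(i + 1L)]
  y <- responses[(i - 1L):(i + 1L)]
  # vertex of the parabola through the three points (Lagrange form)
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d2 - d1) / (x[3] - x[1])
  if (!is.finite(curv) || curv >= 0) return(doses[i])
  vx <- (x[1] + x[2]) / 2 - d1 / (2 * curv)
  if (vx < x[1] || vx > x[3]) return(doses[i])
  vx
}
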