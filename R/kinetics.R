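# Kinetic laws: the two methylation velocities, the Hill activation of the
# methyltransferase, the GSH-dependent reduction rates, and the full ODE
# right-hand side.

#' GSH activation of the methyltransferase
#'
#' Dimensionless activation factor applied to both methylation velocities:
#' a basal activity plus a Hill function of GSH with coefficient 5,
#' `u_basal + k9 * gsh^5 / (k10^5 + gsh^5)`. Monotone nondecreasing in GSH,
#' bounded by `u_basal + k9`; equals `u_basal` at zero GSH and
#' `u_basal + k9/2` at `gsh = k10`.
#'
#' @param gsh GSH concentration, muM (vectorized, nonnegative).
#' @param params a [kinetic_parameters()] object.
#' @return activation factor(s), dimensionless.
#' @examples
#' p <- kinetic_parameters()
#' u_activation(c(0, p$k10, 1e9), p)
#' @export
u_activation <- function(gsh, params) {
  if (any(!is.finite(gsh)) || any(gsh < 0)) {
    stop("gsh must be finite and nonnegative", call. = FALSE)
  }
  h <- (gsh / params$k10)^5
  params$u_basal + params$k9 * h / (1 + h)
}

#' Velocity of the first methylation step (iAs -> MMAsV), pre-activation
#'
#' Michaelis-Menten in iAs with substrate inhibition by iAs and product
#' inhibition by MMAsV:
#' `Vmax * iAs/(Km + iAs) * 1/(1 + iAs/KiA) * 1/(1 + mmasV/KiM)`.
#' The flux used in the ODE is `u_activation(GSH) * v1`. As a function of
#' iAs alone the velocity has an interior maximum at `sqrt(Km * KiA)`.
#'
#' @param iAs free inorganic arsenic, muM (vectorized, nonnegative).
#' @param mmasV free MMAsV, muM (vectorized, nonnegative).
#' @param params a [kinetic_parameters()] object.
#' @return velocity in muM/hr per unit activation.
#' @export
v1 <- function(iAs, mmasV, params) {
  if (any(!is.finite(iAs)) || any(iAs < 0) ||
      any(!is.finite(mmasV)) || any(mmasV < 0)) {
    stop("iAs and mmasV must be finite and nonnegative", call. = FALSE)
  }
  params$Vmax * iAs / (params$Km + iAs) /
    (1 + iAs / params$KiA) / (1 + mmasV / params$KiM)
}

#' Velocity of the second methylation step (MMAsIII -> DMAsV), pre-activation
#'
#' Michaelis-Menten in MMAsIII with inhibition by iAs and cooperative
#' (squared) substrate inhibition by MMAsIII itself:
#' `Vmax * S/(Km + S) * 1/(1 + iAs/KiA2) * 1/(1 + S^2/KiM2^2)` with
#' `S = mmasIII`. The squared term makes the velocity rise then fall in
#' MMAsIII, which is what produces the non-monotone dose-response of the
#' substrate-inhibition sweep experiment.
#'
#' @param mmasIII free MMAsIII, muM (vectorized, nonnegative).
#' @param iAs free inorganic arsenic, muM (vectorized, nonnegative).
#' @param params a [kinetic_parameters()] object.
#' @return velocity in muM/hr per unit activation.
#' @export
v2 <- function(mmasIII, iAs, params) {
  if (any(!is.finite(mmasIII)) || any(mmasIII < 0) ||
      any(!is.finite(iAs)) || any(iAs < 0)) {
    stop("mmasIII and iAs must be finite and nonnegative", call. = FALSE)
  }
  params$Vmax * mmasIII / (params$Km + mmasIII) /
    (1 + iAs / params$KiA2) / (1 + (mmasIII / params$KiM2)^2)
}

#' GSH-dependent reduction rate of MMAsV to MMAsIII
#'
#' First-order rate constant `k5 + k6 * gsh` (per hr): a basal term from
#' endogenous thiols other than GSH plus a term linear in GSH.
#'
#' @inheritParams u_activation
#' @return rate in per hr.
#' @export
reduction_rate_mmas <- function(gsh, params) {
  if (any(!is.finite(gsh)) || any(gsh < 0)) {
    stop("gsh must be finite and nonnegative", call. = FALSE)
  }
  params$k5 + params$k6 * gsh
}

#' GSH-dependent reduction rate of DMAsV to DMAsIII
#'
#' First-order rate constant `k7 + k8 * gsh` (per hr).
#'
#' @inheritParams u_activation
#' @return rate in per hr.
#' @export
reduction_rate_dmas <- function(gsh, params) {
  if (any(!is.finite(gsh)) || any(gsh < 0)) {
    stop("gsh must be finite and nonnegative", call. = FALSE)
  }
  params$k7 + params$k8 * gsh
}

# Unvalidated derivative kernel shared by ode_rhs() and the integrator.
# `u` is the (already evaluated) activation factor. Returns the nine
# derivatives in canonical state order.
.rhs_kernel <- function(s, p, u) {
  g <- s[[7L]]
  V1 <- p$Vmax * s[[1L]] / (p$Km + s[[1L]]) /
    (1 + s[[1L]] / p$KiA) / (1 + s[[2L]] / p$KiM)
  V2 <- p$Vmax * s[[3L]] / (p$Km + s[[3L]]) /
    (1 + s[[1L]] / p$KiA2) / (1 + (s[[3L]] / p$KiM2)^2)
  red_m <- (p$k5 + p$k6 * g) * s[[2L]]
  red_d <- (p$k7 + p$k8 * g) * s[[4L]]
  # net conjugation fluxes (forward - reverse)
  j_atg <- p$k1 * g^3 * s[[1L]] - p$k_1 * s[[6L]]
  j_mg  <- p$k2 * g^2 * s[[3L]] - p$k_2 * s[[8L]]
  j_dg  <- p$k3 * g   * s[[5L]] - p$k_3 * s[[9L]]
  c(-u * V1 - j_atg,                    # iAs
    u * V1 - red_m,                     # MMAsV
    red_m - u * V2 - j_mg,              # MMAsIII
    u * V2 - red_d,                     # DMAsV
    red_d - j_dg,                       # DMAsIII
    j_atg,                              # AsTG
    -p$k4 * g - 3 * j_atg - 2 * j_mg - j_dg,  # GSH
    j_mg,                               # MMAsG
    j_dg)                               # DMAsG
}

#' Right-hand side of the model ODE system
#'
#' Time derivative (muM/hr) of the nine-species state. Methylation fluxes are
#' the activated velocities `U(GSH) * V1` and `U(GSH) * V2`; reductions are
#' first order in the pentavalent species with GSH-dependent rates; the three
#' conjugations are reversible mass action (`k1*GSH^3*iAs` vs `k_1*AsTG`,
#' `k2*GSH^2*MMAsIII` vs `k_2*MMAsG`, `k3*GSH*DMAsIII` vs `k_3*DMAsG`),
#' consuming 3, 2 and 1 GSH respectively; free GSH additionally decays at
#' `k4*GSH`. By construction the eight arsenic derivatives sum to zero and
#' the derivative of [gsh_pool()] equals `-k4*GSH` exactly.
#'
#' @param state a nonnegative named state vector (see [model_state()]).
#' @param params a [kinetic_parameters()] object.
#' @param u optional fixed activation factor overriding `u_activation(GSH)`
#'   (used by the constant-activation model variant).
#' @return named numeric vector of the nine derivatives, muM/hr.
#' @export
ode_rhs <- function(state, params, u = NULL) {
  s <- validate_state(state)
  if (is.null(u)) {
    u <- u_activation(s[["GSH"]], params)
  } else if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0) {
    stop("u must be a nonnegative scalar", call. = FALSE)
  }
  stats::setNames(.rhs_kernel(s, params, u), .state_names)
}
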