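# Model state: the nine concentrations tracked by the ODE system.

.state_names <- c("iAs", "MMAsV", "MMAsIII", "DMAsV", "DMAsIII",
                  "AsTG", "GSH", "MMAsG", "DMAsG")
.arsenic_species <- setdiff(.state_names, "GSH")

#' Construct a model state vector
#'
#' The state of the model is the vector of nine concentrations (muM): free
#' inorganic arsenic `iAs`, the mono- and dimethylated arsenicals in both
#' valences (`MMAsV`, `MMAsIII`, `DMAsV`, `DMAsIII`), free glutathione `GSH`,
#' and the three GSH conjugates `AsTG` (arsenic triglutathione), `MMAsG`
#' (monomethylarsenic diglutathione) and `DMAsG` (dimethylarsenic
#' glutathione). Unspecified components default to zero.
#'
#' @param ... named nonnegative concentrations in muM, e.g.
#'   `model_state(iAs = 1, GSH = 1000)`.
#' @return named numeric vector of length 9 in canonical order.
#' @examples
#' s <- model_state(iAs = 1, GSH = 1000)
#' total_arsenic(s)
#' @export
model_state <- function(...) {
  vals <- list(...)
  s <- stats::setNames(numeric(length(.state_names)), .state_names)
  if (length(vals)) {
    if (is.null(names(vals)) || any(names(vals) == "")) {
      stop("all state components must be named", call. = FALSE)
    }
    unknown <- setdiff(names(vals), .state_names)
    if (length(unknown)) {
      stop("unknown state component(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    s[names(vals)] <- unlist(vals)
  }
  validate_state(s)
}

validate_state <- function(s) {
  if (is.null(names(s)) || !all(.state_names %in% names(s))) {
    stop("state must be named with all of: ", paste(.state_names, collapse = ", "),
         call. = FALSE)
  }
  s <- s[.state_names]
  if (any(!is.finite(s))) stop("state components must be finite", call. = FALSE)
  if (any(s < 0)) stop("state components must be nonnegative", call. = FALSE)
  s
}

#' Put the conjugation reactions of a state at equilibrium
#'
#' Redistributes each free arsenical and its GSH conjugate (iAs/AsTG,
#' MMAsIII/MMAsG, DMAsIII/DMAsG) at the reversible mass-action equilibrium
#' for the state's GSH level, keeping each pool's total arsenic fixed and
#' adjusting free GSH by the stoichiometric amount bound (3, 2, 1 per
#' conjugate). Iterated to self-consistency in GSH. Used to remove the
#' mixing transient from experiments where the binding timescale (seconds at
#' mM GSH) is far below the observation timescale.
#'
#' @param state a model state (named vector).
#' @param params a [kinetic_parameters()] object.
#' @param iterations fixed-point iterations on the free-GSH level.
#' @return the equilibrated state (same totals per pool, same total GSH
#'   equivalents up to the binding stoichiometry).
#' @export
equilibrate_conjugates <- function(state, params, iterations = 25L) {
  s <- validate_state(state)
  pool_i <- s[["iAs"]] + s[["AsTG"]]
  pool_m <- s[["MMAsIII"]] + s[["MMAsG"]]
  pool_d <- s[["DMAsIII"]] + s[["DMAsG"]]
  gsh_eq <- gsh_pool(s)
  g <- s[["GSH"]]
  for (i in seq_len(iterations)) {
    f_i <- params$k1 * g^3 / (params$k1 * g^3 + params$k_1)
    f_m <- params$k2 * g^2 / (params$k2 * g^2 + params$k_2)
    f_d <- params$k3 * g / (params$k3 * g + params$k_3)
    bound <- 3 * f_i * pool_i + 2 * f_m * pool_m + f_d * pool_d
    g <- max(gsh_eq - bound, 0)
  }
  s[["AsTG"]] <- f_i * pool_i;    s[["iAs"]] <- pool_i - s[["AsTG"]]
  s[["MMAsG"]] <- f_m * pool_m;   s[["MMAsIII"]] <- pool_m - s[["MMAsG"]]
  s[["DMAsG"]] <- f_d * pool_d;   s[["DMAsIII"]] <- pool_d - s[["DMAsG"]]
  s[["GSH"]] <- g
  s
}

#' Total arsenic in a state
#'
#' Sum of the eight arsenic-carrying species (every species except GSH carries
#' exactly one arsenic atom). The model has no export terms, so this quantity
#' is conserved along every trajectory.
#'
#' @param state a model state (named vector) or a matrix/data frame with the
#'   nine state columns (one row per time point).
#' @return total arsenic in muM (scalar or per-row vector).
#' @export
total_arsenic <- function(state) {
  if (is.matrix(state) || is.data.frame(state)) {
    rowSums(as.matrix(state[, .arsenic_species, drop = FALSE]))
  } else {
    sum(state[.arsenic_species])
  }
}

#' Glutathione equivalents in a state
#'
#' Stoichiometric GSH pool: free GSH plus 3 per AsTG, 2 per MMAsG and 1 per
#' DMAsG. With the decay constant `k4 = 0` this pool is conserved; with
#' `k4 > 0` it decreases at exactly `k4 * GSH` (conjugation only moves GSH
#' between the free and bound pools).
#'
#' @inheritParams total_arsenic
#' @return GSH equivalents in muM (scalar or per-row vector).
#' @export
gsh_pool <- function(state) {
  if (is.matrix(state) || is.data.frame(state)) {
    m <- as.matrix(state)
    m[, "GSH"] + 3 * m[, "AsTG"] + 2 * m[, "MMAsG"] + m[, "DMAsG"]
  } else {
    state[["GSH"]] + 3 * state[["AsTG"]] + 2 * state[["MMAsG"]] + state[["DMAsG"]]
  }
}
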