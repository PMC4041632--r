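# Synthetic assay datasets: forward simulation of a preset design plus a
# conjugate-blind observation model with proportional noise.

#' Design of a synthetic assay
#'
#' A design names a preset experiment and its grid. Supported presets and
#' their observed (conjugate-blind) readouts:
#' * `"mmas_sweep"`: fields `gsh_mM`, `doses` (muM MMAsIII), optional
#'   `horizon_h`; readouts `trivalent_DMAs`, `total_DMAs`.
#' * `"gsh_dose_response"`: field `doses_mM`; readouts `total_MMAs`,
#'   `total_DMAs`, `total_methylated`.
#' * `"time_course"`: fields `gsh_mM`, optional `n_times`; readouts
#'   `iAs_like`, `total_MMAs`, `trivalent_MMAs`, `total_DMAs`,
#'   `trivalent_DMAs`.
#'
#' @param preset one of the preset names above.
#' @param ... design fields (see above).
#' @return a design list of class `assay_design`.
#' @export
assay_design <- function(preset = c("mmas_sweep", "gsh_dose_response",
                                    "time_course"), ...) {
  preset <- match.arg(preset)
  structure(c(list(preset = preset), list(...)), class = "assay_design")
}

.design_readouts <- function(design) {
  switch(design$preset,
    mmas_sweep = c("trivalent_DMAs", "total_DMAs"),
    gsh_dose_response = c("total_MMAs", "total_DMAs", "total_methylated"),
    time_course = c("iAs_like", "total_MMAs", "trivalent_MMAs",
                    "total_DMAs", "trivalent_DMAs"))
}

#' Noise-free readouts of an assay design
#'
#' Forward-simulates `design` under `params` and returns one row per design
#' point (dose or readout time) with the observable readout columns.
#'
#' @param design an [assay_design()].
#' @param params a [kinetic_parameters()] object.
#' @return data frame: design abscissa first (`dose`, `dose_mM` or
#'   `time_h`), then the readout columns.
#' @export
simulate_design <- function(design, params) {
  switch(design$preset,
    mmas_sweep = {
      tab <- mmas_sweep(design$gsh_mM %||% 0,
                        design$doses %||% seq(0, 20, by = 0.5),
                        params, horizon_h = design$horizon_h %||% 1)
      tab[, c("dose", .design_readouts(design))]
    },
    gsh_dose_response = {
      gsh_dose_response(design$doses_mM %||% c(1, 3, 5, 7, 10, 20),
                        params)$table[, c("dose_mM", .design_readouts(design))]
    },
    time_course = {
      r <- time_course(design$gsh_mM %||% 0, params,
                       n_times = design$n_times %||% 9L)
      cbind(data.frame(time_h = r$times),
            r$derived[, .design_readouts(design)])
    })
}

#' Apply the observation noise model to noise-free readouts
#'
#' Each readout is multiplied by an independent noise factor: Gaussian with
#' mean 1 and standard deviation `cv` (truncated so observations stay
#' nonnegative) or, alternatively, log-normal with unit mean and the same
#' coefficient of variation.
#'
#' @param truth data frame of noise-free readouts.
#' @param readouts names of the columns to perturb.
#' @param cv coefficient of variation in `[0, 1)`.
#' @param seed integer seed.
#' @param noise `"proportional"` (truncated Gaussian factor) or
#'   `"lognormal"`.
#' @return data frame like `truth` with perturbed readout columns.
#' @export
apply_observation_noise <- function(truth, readouts, cv, seed,
                                    noise = c("proportional", "lognormal")) {
  noise <- match.arg(noise)
  if (!is.numeric(cv) || cv < 0 || cv >= 1) {
    stop("cv must lie in [0, 1)", call. = FALSE)
  }
  obs <- truth
  set.seed(as.integer(seed))
  for (col in readouts) {
    n <- nrow(truth)
    fac <- if (cv == 0) {
      rep(1, n)
    } else if (noise == "proportional") {
      stats::rnorm(n, mean = 1, sd = cv)
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    obs[[col]] <- pmax(truth[[col]] * fac, 0)
  }
  obs
}

#' Generate a synthetic assay dataset
#'
#' Simulates `design` under `true_params` and applies the observation model.
#' Everything needed to regenerate the dataset bit-identically (design, true
#' parameters, noise descriptor, seed) is recorded on the object.
#'
#' @param design an [assay_design()].
#' @param true_params the generating [kinetic_parameters()].
#' @param cv coefficient of variation of the proportional noise, `[0, 1)`.
#' @param seed integer seed.
#' @param noise noise model, see [apply_observation_noise()].
#' @return object of class `synthetic_dataset`: `design`, `truth`,
#'   `observations`, `readouts`, `cv`, `noise`, `seed`, `true_params`.
#' @export
generate_dataset <- function(design, true_params = kinetic_parameters(),
                             cv = 0.1, seed = 1L,
                             noise = c("proportional", "lognormal")) {
  noise <- match.arg(noise)
  validate_parameters(true_params)
  truth <- simulate_design(design, true_params)
  readouts <- .design_readouts(design)
  observations <- apply_observation_noise(truth, readouts, cv, seed, noise)
  structure(list(design = design, truth = truth, observations = observations,
                 readouts = readouts, cv = cv, noise = noise,
                 seed = as.integer(seed), true_params = true_params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic assay dataset: preset '", x$design$preset, "', ",
      nrow(x$observations), " design points, cv = ", x$cv,
      " (", x$noise, "), seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic dataset (CSV + JSON sidecar)
#'
#' The CSV holds the design abscissa, the noise-free readouts and the
#' observed readouts (columns prefixed `observed_`), at full precision. The
#' sidecar (`<path>.json`) records the design, noise descriptor, seed and
#' the complete generating parameter set, so the dataset can be regenerated
#' from the sidecar alone.
#'
#' @param dataset a [generate_dataset()] object.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   reconstructed `synthetic_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  tab <- dataset$truth
  for (col in dataset$readouts) {
    tab[[paste0("observed_", col)]] <- dataset$observations[[col]]
  }
  .write_csv_full_precision(tab, path)
  pvec <- unlist(unclass(dataset$true_params))
  side <- list(design = unclass(dataset$design), readouts = dataset$readouts,
               cv = dataset$cv, noise = dataset$noise, seed = dataset$seed,
               # exact decimal strings: JSON numbers do not round-trip doubles
               true_params = as.list(stats::setNames(.format_shortest(pvec),
                                                     names(pvec))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  readouts <- side$readouts
  truth <- tab[, setdiff(names(tab), paste0("observed_", readouts)),
               drop = FALSE]
  observations <- truth
  for (col in readouts) observations[[col]] <- tab[[paste0("observed_", col)]]
  design <- structure(lapply(side$design, function(x) unlist(x)),
                      class = "assay_design")
  params <- do.call(kinetic_parameters, lapply(side$true_params, as.numeric))
  structure(list(design = design, truth = truth, observations = observations,
                 readouts = readouts, cv = side$cv, noise = side$noise,
                 seed = as.integer(side$seed), true_params = params),
            class = "synthetic_dataset")
}
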