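# Structured-text parameter files and CSV + JSON-sidecar result output.

# shortest decimal representation that parses back to the identical double
.format_shortest <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x & is.finite(x)
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

# full-precision CSV: numerics formatted so a write/read round-trip is
# lossless
.write_csv_full_precision <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .format_shortest(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a parameter file
#'
#' Flat structured-text format, one `key = value` pair per line; `#` starts
#' a comment. Values are written with full precision. The shipped defaults
#' file (`system.file("extdata", "default_parameters.conf", package =
#' "arsmet")`) carries the default parameterization.
#'
#' @param params a [kinetic_parameters()] object.
#' @param path file path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters` a
#'   validated `kinetic_parameters` object.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  lines <- c("# arsmet kinetic parameters (concentrations muM, time hours)",
             vapply(.param_names, function(nm) {
               sprintf("%s = %s", nm, .format_shortest(params[[nm]]))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed parameter line: '", ln, "'", call. = FALSE)
    }
    key <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val)) stop("non-numeric value for ", key, call. = FALSE)
    vals[[key]] <- val
  }
  do.call(kinetic_parameters, vals)
}

#' Write a result table with a provenance sidecar
#'
#' Writes `table` as a comma-separated, '.'-decimal, header-first UTF-8 CSV
#' (full numeric precision) and a JSON sidecar `<path>.json` recording the
#' experiment description, the complete parameter set and its hash, solver
#' tolerances and the package version, so every output file is reproducible
#' from its sidecar alone.
#'
#' @param table data frame (time or dose in the first column).
#' @param path CSV path.
#' @param spec_info list describing the experiment (label, variant, grids...).
#' @param params the [kinetic_parameters()] used.
#' @param rtol,atol solver tolerances used.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(table, path, spec_info = list(),
                             params = kinetic_parameters(),
                             rtol = 1e-8, atol = 1e-10) {
  .write_csv_full_precision(table, path)
  pvec <- unlist(unclass(params))
  side <- list(
    spec = spec_info,
    # formatted as shortest exact decimals: JSON numeric serialization does
    # not round-trip doubles bit-exactly
    parameters = as.list(stats::setNames(.format_shortest(pvec), names(pvec))),
    parameter_hash = {
      chars <- utf8ToInt(paste(.format_shortest(pvec), collapse = ","))
      sprintf("%08x", sum(chars * seq_along(chars)) %% 2^31)
    },
    solver = list(method = "lsoda", rtol = rtol, atol = atol),
    package_version = as.character(utils::packageVersion("arsmet")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a result CSV written by [write_result_csv()]
#'
#' @param path CSV path.
#' @return data frame; the parsed sidecar is attached as attribute
#'   `"sidecar"` when present.
#' @export
read_result_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    attr(df, "sidecar") <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  df
}
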