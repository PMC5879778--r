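## Result serialization: CSV for tabular outputs, JSON for summaries and
## run manifests.  CSV dialect: comma-separated, UTF-8, '.' decimal,
## mandatory header row; units are carried in the column names.

#' Write results to disk
#'
#' Dispatches on the result class: trajectories, characterisation curves
#' and DGSM tables become CSV files with stable column order; campaign
#' objects write a records CSV plus a JSON summary next to it.
#'
#' @param x a result object (`cc_trajectory`, `cc_curve`, `cc_dgsm`,
#'   `cc_campaign`).
#' @param path output file path (for campaigns, the records CSV; the
#'   summary lands at the same path with extension `.summary.json`).
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.cc_trajectory <- function(x, path, ...) {
  df <- as.data.frame(x)[, c("time_h", .species, "hif1a", "hif2a", "deg")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_results.cc_curve <- function(x, path, ...) {
  df <- data.frame(o2_fraction = x$o2, committed = x$committed,
                   ct_h = x$ct)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_results.cc_dgsm <- function(x, path, ...) {
  df <- data.frame(o2_fraction = x$o2_fraction, symbol = x$symbol,
                   G_score = x$G_score, n_samples = x$n_samples)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_results.cc_campaign <- function(x, path, ...) {
  utils::write.csv(x$records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(x$summary, sub("\\.csv$", "", path) %+%
                         ".summary.json",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)

#' Write a run manifest
#'
#' JSON manifest sufficient to reproduce a run bitwise: configuration
#' echo, parameter hash, package version, timestamp and per-stage counts.
#'
#' @param config named list echoing the run configuration (grids, sample
#'   counts, Sobol skip, tolerances).
#' @param p the `cc_params` used.
#' @param path output path.
#' @param counts optional named list of per-stage counts (runs,
#'   exclusions, failures).
#' @return `path`, invisibly.
#' @export
run_manifest <- function(config, p, path, counts = list()) {
  stopifnot(inherits(p, "cc_params"))
  man <- list(
    package = "hifcycle",
    version = as.character(utils::packageVersion("hifcycle")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameter_hash = parameter_hash(p),
    solver = .solver_defaults,
    config = config,
    counts = counts)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
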