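## Parameter handling: symbol table, constructor, validation, JSON round-trip.

## Master symbol table. `symbol` is the notation used in the model description
## and in parameter files; `internal` is the syntactic R name used in code.
.symbol_table <- data.frame(
  symbol = c(
    "m1", "b1", "p1", "t1", "m2", "b2", "p2", "t2",
    "kf3A", "kr3A", "kf3B", "kr3B", "kf6B", "kr6B", "kf12", "kr12", "k8",
    "m9", "k9", "m13", "k13", "k'13",
    "m_E2F", "k_E2F", "m_E2F-RbP", "k_E2F-RbP",
    "m_5cycD", "k_5cycD", "m_cycD-Rb", "k_cycD-Rb",
    "m_RbP", "k_RbP", "m_cycE-RbP", "k_cycE-RbP",
    "m_Rb-nP", "k_Rb-nP",
    "k3a", "k4", "epsilon",
    "g_Myc", "g_cycD", "g_p/p", "g_Rb",
    "d_Myc", "d_Hif1a-Myc", "d_Hif2a-Myc", "d_cycE", "d_E2F", "d_cycD",
    "d_p/p", "d_cycD-p/p", "d_cycE-p/p", "d_Rb", "d_E2F-Rb", "d_RbP",
    "n", "n_deg", "[O2]_TH", "E2F_TH"),
  internal = c(
    "m1", "b1", "p1", "t1", "m2", "b2", "p2", "t2",
    "kf3A", "kr3A", "kf3B", "kr3B", "kf6B", "kr6B", "kf12", "kr12", "k8",
    "m9", "k9", "m13", "k13", "kp13",
    "m_E2F", "k_E2F", "m_E2F_RbP", "k_E2F_RbP",
    "m_5cycD", "k_5cycD", "m_cycD_Rb", "k_cycD_Rb",
    "m_RbP", "k_RbP", "m_cycE_RbP", "k_cycE_RbP",
    "m_Rb_nP", "k_Rb_nP",
    "k3a", "k4", "eps",
    "g_Myc", "g_cycD", "g_pp", "g_Rb",
    "d_Myc", "d_H1M", "d_H2M", "d_cycE", "d_E2F", "d_cycD",
    "d_pp", "d_cycD_pp", "d_cycE_pp", "d_Rb", "d_E2F_Rb", "d_RbP",
    "n", "n_deg", "o2_th", "e2f_threshold"),
  block = c(rep("hif", 8), rep("kinetics", 48), "ros", "ros", "threshold"),
  stringsAsFactors = FALSE)

## Species in fixed state-vector order (matches the C right-hand side).
.species <- c("hif1a_myc", "hif2a_myc", "myc", "cycE", "e2f", "cycD", "pp",
              "cycD_pp", "cycE_pp", "rb", "e2f_rb", "rbP", "rb_nP")

## Display names used in parameter files for initial conditions.
.species_symbols <- c("Hif1a-Myc", "Hif2a-Myc", "Myc", "cycE", "E2F", "cycD",
                      "p/p", "cycD-p/p", "cycE-p/p", "Rb", "E2F-Rb", "RbP",
                      "Rb-nP")

.internal_of <- function(symbol) {
  i <- match(symbol, .symbol_table$symbol)
  miss <- is.na(i)
  ## also accept internal names directly
  i[miss] <- match(symbol[miss], .symbol_table$internal)
  if (anyNA(i))
    stop("unknown parameter symbol(s): ",
         paste(symbol[is.na(i)], collapse = ", "), call. = FALSE)
  .symbol_table$internal[i]
}

.symbol_of <- function(internal) {
  .symbol_table$symbol[match(internal, .symbol_table$internal)]
}

#' Construct a model parameter set
#'
#' Builds the complete parameter set of the hypoxia-commitment model: the
#' Hif1a/Hif2a oxygen-response constants, the kinetic constants of the
#' 13-species Myc-Rb-E2F network, the ROS deactivation parameters, the E2F
#' commitment threshold, and the default initial conditions.  With no
#' arguments, the nominal calibration shipped with the package is returned.
#'
#' Parameters may be addressed either by their model symbol (e.g. `"k'13"`,
#' `"m_E2F-RbP"`, `"[O2]_TH"`, `"epsilon"`) or by the equivalent syntactic
#' name (`"kp13"`, `"m_E2F_RbP"`, `"o2_th"`, `"eps"`).
#'
#' @param ... named overrides, `symbol = value`.
#' @param file optional path to a parameter JSON file; defaults to the
#'   nominal fixture shipped in `inst/extdata/`.
#' @param init optional named numeric vector of initial concentrations
#'   (micromolar) for the 13 species, replacing the file's defaults.
#' @param unify_k_e2f_rbp logical; the printed rate law for cyclin-D-driven
#'   E2F-Rb dissociation carries the half-saturation constant `k_cycE-RbP`
#'   in the hypo-phosphorylated-Rb balance but `k_E2F-RbP` in the E2F and
#'   E2F-Rb balances.  The default (`FALSE`) keeps both as written; `TRUE`
#'   uses `k_E2F-RbP` throughout.
#' @return an object of class `cc_params`.
#' @export
#' @examples
#' p <- cc_parameters()
#' p2 <- cc_parameters("n_deg" = 0.01)
cc_parameters <- function(..., file = NULL, init = NULL,
                          unify_k_e2f_rbp = FALSE) {
  if (is.null(file))
    file <- system.file("extdata", "params_nominal.json",
                        package = "hifcycle", mustWork = TRUE)
  p <- load_parameters(file)
  p$unify_k_e2f_rbp <- isTRUE(unify_k_e2f_rbp)
  over <- list(...)
  if (length(over)) p <- do.call(cc_set, c(list(p), over))
  if (!is.null(init)) {
    stopifnot(is.numeric(init), !is.null(names(init)))
    bad <- setdiff(names(init), .species)
    if (length(bad)) stop("unknown species in init: ",
                          paste(bad, collapse = ", "))
    p$init[names(init)] <- init
    p <- .validate_params(p)
  }
  p
}

#' Read or modify parameter values by symbol
#'
#' @param p a `cc_params` object.
#' @param symbol parameter symbol (model notation or syntactic name).
#' @return `cc_get` returns the numeric value; `cc_set` returns the modified,
#'   re-validated parameter set.
#' @export
cc_get <- function(p, symbol) {
  stopifnot(inherits(p, "cc_params"))
  int <- .internal_of(symbol)
  out <- numeric(length(int))
  for (j in seq_along(int)) {
    blk <- .symbol_table$block[match(int[j], .symbol_table$internal)]
    out[j] <- switch(blk,
      hif = p$hif[[int[j]]],
      kinetics = p$kinetics[[int[j]]],
      ros = p$ros[[int[j]]],
      threshold = p$e2f_threshold)
  }
  names(out) <- symbol
  out
}

#' @rdname cc_get
#' @param ... named `symbol = value` pairs.
#' @export
cc_set <- function(p, ...) {
  stopifnot(inherits(p, "cc_params"))
  over <- list(...)
  if (!length(over)) return(p)
  if (is.null(names(over)) || any(names(over) == ""))
    stop("all overrides must be named")
  int <- .internal_of(names(over))
  for (j in seq_along(int)) {
    blk <- .symbol_table$block[match(int[j], .symbol_table$internal)]
    v <- as.numeric(over[[j]])
    switch(blk,
      hif = { p$hif[[int[j]]] <- v },
      kinetics = { p$kinetics[[int[j]]] <- v },
      ros = { p$ros[[int[j]]] <- v },
      threshold = { p$e2f_threshold <- v })
  }
  .validate_params(p)
}

.validate_params <- function(p) {
  need <- split(.symbol_table$internal, .symbol_table$block)
  for (nm in need$hif)
    if (is.null(p$hif[[nm]])) stop("missing parameter: ", .symbol_of(nm))
  for (nm in need$kinetics)
    if (is.null(p$kinetics[[nm]])) stop("missing parameter: ", .symbol_of(nm))
  for (nm in need$ros)
    if (is.null(p$ros[[nm]])) stop("missing parameter: ", .symbol_of(nm))
  if (is.null(p$e2f_threshold)) stop("missing parameter: E2F_TH")

  h <- p$hif; k <- p$kinetics; r <- p$ros
  all_vals <- c(unlist(h), unlist(k), unlist(r), p$e2f_threshold)
  if (!all(is.finite(all_vals))) stop("non-finite parameter value")
  if (any(all_vals < 0)) {
    bad <- names(all_vals)[all_vals < 0]
    stop("negative parameter value: ", paste(.symbol_of(bad), collapse = ", "))
  }
  if (h$t1 <= 0 || h$t2 <= 0) stop("normalization oxygen t1, t2 must be > 0")
  halfsat <- c("k9", "k13", "kp13", "k_E2F", "k_E2F_RbP", "k_5cycD",
               "k_cycD_Rb", "k_RbP", "k_cycE_RbP", "k_Rb_nP", "k3a")
  for (nm in halfsat)
    if (k[[nm]] <= 0) stop("half-saturation constant must be > 0: ",
                           .symbol_of(nm))
  if (k$n < 2 || k$n != round(k$n))
    stop("hyper-phosphorylation order n must be an integer >= 2")
  if (r$o2_th <= 0 || r$o2_th > 0.21)
    stop("[O2]_TH must lie in (0, 0.21]")
  if (p$e2f_threshold <= 0) stop("E2F_TH must be > 0")
  if (length(p$init) != length(.species) ||
      !setequal(names(p$init), .species))
    stop("initial conditions must cover exactly the 13 model species")
  p$init <- p$init[.species]
  if (any(!is.finite(p$init)) || any(p$init < 0))
    stop("initial concentrations must be finite and non-negative")
  structure(p, class = "cc_params")
}

#' Load a parameter file
#'
#' Reads a JSON parameter file keyed by model symbols (see
#' [cc_parameters()]), validates completeness and sign constraints, and
#' returns a `cc_params` object.  A missing hyper-phosphorylation order `n`
#' defaults to 4; every other symbol is required.
#'
#' @param path path to the JSON file.
#' @return a `cc_params` object.
#' @export
load_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- raw$parameters
  if (is.null(vals)) stop("parameter file has no 'parameters' block")
  known <- .symbol_table$symbol
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown symbol(s) in parameter file: ",
         paste(unknown, collapse = ", "))
  if (is.null(vals[["n"]])) vals[["n"]] <- 4
  missing_sym <- setdiff(known, names(vals))
  if (length(missing_sym))
    stop("parameter file is missing symbol(s): ",
         paste(missing_sym, collapse = ", "))

  int <- .internal_of(names(vals))
  blk <- .symbol_table$block[match(int, .symbol_table$internal)]
  num <- vapply(vals, as.numeric, numeric(1))
  p <- list(
    hif = as.list(stats::setNames(num[blk == "hif"], int[blk == "hif"])),
    kinetics = as.list(stats::setNames(num[blk == "kinetics"],
                                       int[blk == "kinetics"])),
    ros = as.list(stats::setNames(num[blk == "ros"], int[blk == "ros"])),
    e2f_threshold = unname(num[int == "e2f_threshold"]),
    unify_k_e2f_rbp = isTRUE(raw$unify_k_e2f_rbp))

  ic <- raw$initial_conditions
  if (is.null(ic)) stop("parameter file has no 'initial_conditions' block")
  idx <- match(names(ic), .species_symbols)
  if (anyNA(idx))
    stop("unknown species in initial_conditions: ",
         paste(names(ic)[is.na(idx)], collapse = ", "))
  init <- rep(NA_real_, length(.species))
  names(init) <- .species
  init[idx] <- vapply(ic, as.numeric, numeric(1))
  if (anyNA(init))
    stop("initial_conditions missing species: ",
         paste(.species_symbols[is.na(init)], collapse = ", "))
  p$init <- init
  .validate_params(p)
}

#' Write a parameter set to JSON
#'
#' Inverse of [load_parameters()]; the written file round-trips through
#' [load_parameters()] unchanged (up to key order).
#'
#' @param p a `cc_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(p, path) {
  stopifnot(inherits(p, "cc_params"))
  int <- .symbol_table$internal
  blk <- .symbol_table$block
  vals <- numeric(length(int))
  for (j in seq_along(int)) {
    vals[j] <- switch(blk[j],
      hif = p$hif[[int[j]]],
      kinetics = p$kinetics[[int[j]]],
      ros = p$ros[[int[j]]],
      threshold = p$e2f_threshold)
  }
  out <- list(
    units = list(concentration = "uM", time = "h",
                 oxygen = "fraction (0.02 = 2%)"),
    parameters = as.list(stats::setNames(vals, .symbol_table$symbol)),
    initial_conditions = as.list(stats::setNames(unname(p$init),
                                                 .species_symbols)),
    unify_k_e2f_rbp = isTRUE(p$unify_k_e2f_rbp))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Content hash of a parameter set
#'
#' MD5 digest of the canonical JSON serialization; used to tag trajectories,
#' curves and campaign records so results can be traced to the exact
#' parameter values that produced them.
#'
#' @param p a `cc_params` object.
#' @return a character scalar.
#' @export
parameter_hash <- function(p) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_parameters(p, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.cc_params <- function(x, ...) {
  cat("Hypoxia cell-cycle commitment model parameters\n")
  cat(sprintf("  Hif1a: peak %.3g uM at %.2g%% O2 (b1 = %.3g, t1 = %.3g)\n",
              x$hif$m1 * exp(x$hif$b1), 100 * x$hif$p1, x$hif$b1, x$hif$t1))
  cat(sprintf("  Hif2a: peak %.3g uM at %.2g%% O2 (b2 = %.3g, t2 = %.3g)\n",
              x$hif$m2 * exp(x$hif$b2), 100 * x$hif$p2, x$hif$b2, x$hif$t2))
  cat(sprintf("  ROS:   n_deg = %.3g, activation threshold %.2g%% O2\n",
              x$ros$n_deg, 100 * x$ros$o2_th))
  cat(sprintf("  E2F commitment threshold: %.3g uM\n", x$e2f_threshold))
  cat(sprintf("  kinetic constants: %d; hash %s\n",
              length(x$kinetics), substr(parameter_hash(x), 1, 8)))
  invisible(x)
}
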