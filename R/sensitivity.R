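## Derivative-based global sensitivity measures (DGSM).
##
## The elementary quantity is a relative-perturbation forward difference
##   E_i = (f(x_i * (1 + d)) - f(x)) / d,
## exactly as the model description defines it: the difference is divided
## by the relative step d alone, not by x_i * d, so E_i carries the scale
## of x_i (a semi-elasticity).  g_i averages E_i^2 over the parameter
## hypercube by quasi-Monte-Carlo integration on Sobol points, and the
## G-scores are the normalised g_i, summing to one by construction.

## CT-at-fixed-oxygen objective over a parameter space
.ct_objective <- function(p, space, o2, t_max = 200) {
  stopifnot(inherits(p, "cc_params"), inherits(space, "cc_space"))
  .check_o2(o2)
  int <- .internal_of(space$symbols)
  blk <- .symbol_table$block[match(int, .symbol_table$internal)]
  init <- p$init[.species]
  function(x) {
    q <- p
    for (j in seq_along(int)) {
      v <- x[j]
      switch(blk[j],
        hif = { q$hif[[int[j]]] <- v },
        kinetics = { q$kinetics[[int[j]]] <- v },
        ros = { q$ros[[int[j]]] <- v },
        threshold = { q$e2f_threshold <- v })
    }
    .ct_fast(.pack_parms(q, o2), init, t_max)
  }
}

#' Relative-perturbation local derivative
#'
#' Forward difference of an objective under a relative perturbation of one
#' coordinate: `E_i = (f(x with x_i*(1+d)) - f(x)) / d`.  Note the division
#' by the relative step `d` alone (not by `x_i * d`): for smooth `f`,
#' `E_i -> x_i * df/dx_i` as `d -> 0`.
#'
#' @param f objective function taking a numeric vector.
#' @param x evaluation point (numeric vector).
#' @param i coordinate index to perturb.
#' @param d relative step (> 0), default 0.01.
#' @param f0 optional precomputed `f(x)`.
#' @return numeric `E_i`; `NA` if either evaluation is undefined.
#' @export
local_derivative <- function(f, x, i, d = 0.01, f0 = NULL) {
  stopifnot(d > 0, i >= 1, i <= length(x))
  if (is.null(f0)) f0 <- f(x)
  if (is.na(f0)) return(NA_real_)
  xp <- x
  xp[i] <- xp[i] * (1 + d)
  f1 <- f(xp)
  if (is.na(f1)) return(NA_real_)
  (f1 - f0) / d
}

#' G-scores at a fixed oxygen level
#'
#' Estimates the DGSM sensitivities of commitment time with respect to the
#' parameters of `space` at one oxygen tension.  Sobol points are added in
#' batches; after each batch the G-scores are recomputed and the run stops
#' once the largest change between consecutive batches drops below `tol`
#' (or `n_max` points are reached).  A Sobol point at which the commitment
#' time is undefined (quiescent) before or after any perturbation is
#' excluded from the averages and counted.
#'
#' @param p a `cc_params` object.
#' @param space a `cc_space` (defaults to the P1-P8 hypercube).
#' @param o2 oxygen tension (fraction).
#' @param d relative perturbation step.
#' @param batch points per convergence batch.
#' @param tol convergence tolerance on `max |delta G_i|`.
#' @param n_max cap on total Sobol points.
#' @param t_max commitment horizon (hours).
#' @param skip Sobol skip (initial points discarded).
#' @param objective optional objective overriding the CT objective (used
#'   for validation with analytic functions).
#' @return a `cc_sens`: list with `o2`, `symbols`, `g`, `G`, sample
#'   accounting, per-batch `history` and the convergence flag.
#' @export
g_scores <- function(p = NULL, space = NULL, o2, d = 0.01, batch = 500,
                     tol = 0.01, n_max = 39000, t_max = 200, skip = 0,
                     objective = NULL) {
  if (is.null(space)) space <- parameter_space(p)
  f <- if (is.null(objective)) .ct_objective(p, space, o2, t_max)
       else objective
  dim <- space$dim
  sums <- numeric(dim)
  n_used <- 0L; n_total <- 0L
  G_prev <- NULL
  history <- NULL
  converged <- FALSE
  while (n_total < n_max && !converged) {
    nb <- min(batch, n_max - n_total)
    pts <- sobol_points(nb, space = space, skip = skip + n_total)
    for (r in seq_len(nb)) {
      x <- pts[r, ]
      f0 <- f(x)
      if (is.na(f0)) { n_total <- n_total + 1L; next }
      E <- numeric(dim)
      ok <- TRUE
      for (j in seq_len(dim)) {
        E[j] <- local_derivative(f, x, j, d, f0 = f0)
        if (is.na(E[j])) { ok <- FALSE; break }
      }
      n_total <- n_total + 1L
      if (!ok) next
      sums <- sums + E^2
      n_used <- n_used + 1L
    }
    if (n_used == 0 || n_used / n_total < 0.10)
      stop(sprintf(
        "regime unsuitable: only %d of %d Sobol points have a defined commitment time at o2 = %.3g",
        n_used, n_total, o2))
    g <- sums / n_used
    G <- g / sum(g)
    history <- rbind(history, G)
    if (!is.null(G_prev) && max(abs(G - G_prev)) < tol) converged <- TRUE
    G_prev <- G
  }
  rownames(history) <- NULL
  colnames(history) <- space$symbols
  structure(list(o2 = o2, symbols = space$symbols,
                 g = stats::setNames(g, space$symbols),
                 G = stats::setNames(G, space$symbols),
                 n_total = n_total, n_used = n_used,
                 n_excluded = n_total - n_used,
                 d = d, batch = batch, tol = tol,
                 history = history, converged = converged),
            class = "cc_sens")
}

#' Local-sensitivity screening of all model parameters
#'
#' Ranks every model parameter by the magnitude of its relative-perturbation
#' local derivative of commitment time at the nominal point, maximised over
#' a set of oxygen levels.  Used as a cheap preliminary screen to select
#' the subset subjected to the full DGSM analysis.
#'
#' @param p a `cc_params` object.
#' @param o2_levels oxygen tensions over which the score is maximised.
#' @param top_k number of top-ranked symbols to return.
#' @param d relative perturbation step.
#' @param t_max commitment horizon.
#' @return data frame with `symbol` and `score`, ordered by decreasing
#'   score, truncated to `top_k` rows.
#' @export
screen_parameters <- function(p, o2_levels = c(0.02, 0.05, 0.1, 0.2),
                              top_k = 8, d = 0.01, t_max = 200) {
  stopifnot(inherits(p, "cc_params"))
  syms <- setdiff(.symbol_table$symbol, "n")  # integer order not perturbed
  score <- stats::setNames(rep(0, length(syms)), syms)
  init <- p$init[.species]
  any_defined <- FALSE
  for (o2 in o2_levels) {
    f0 <- .ct_fast(.pack_parms(p, o2), init, t_max)
    if (is.na(f0)) next
    any_defined <- TRUE
    for (s in syms) {
      x0 <- unname(cc_get(p, s))
      if (x0 == 0) next
      q <- do.call(cc_set, stats::setNames(list(p, x0 * (1 + d)),
                                           c("", s)))
      f1 <- .ct_fast(.pack_parms(q, o2), init, t_max)
      if (is.na(f1)) next
      score[s] <- max(score[s], abs((f1 - f0) / d))
    }
  }
  if (!any_defined)
    stop("commitment time undefined at the nominal point for every ",
         "supplied oxygen level")
  ord <- order(score, decreasing = TRUE)
  utils::head(data.frame(symbol = syms[ord], score = unname(score[ord]),
                         row.names = NULL), top_k)
}

#' DGSM study across oxygen levels
#'
#' Runs [g_scores()] at each oxygen level (the standard seven span severe
#' hypoxia to normoxia) and assembles a long-format table of converged
#' G-scores.  Failures at individual levels are reported and do not stop
#' the remaining levels.
#'
#' @inheritParams g_scores
#' @param o2_levels oxygen tensions.
#' @return a `cc_dgsm`: data frame with columns `o2_fraction`, `symbol`,
#'   `g`, `G_score`, `n_samples`, `n_excluded`; per-level `cc_sens`
#'   objects in `attr(, "levels")`.
#' @export
dgsm_study <- function(p, space = NULL,
                       o2_levels = c(0.01, 0.02, 0.05, 0.08, 0.1, 0.15, 0.2),
                       d = 0.01, batch = 500, tol = 0.01, n_max = 39000,
                       t_max = 200, skip = 0) {
  if (is.null(space)) space <- parameter_space(p)
  res <- list(); rows <- list()
  for (o2 in o2_levels) {
    key <- sprintf("%.6g", o2)
    r <- tryCatch(
      g_scores(p, space, o2, d = d, batch = batch, tol = tol,
               n_max = n_max, t_max = t_max, skip = skip),
      error = function(e) e)
    if (inherits(r, "error")) {
      warning(sprintf("o2 = %s: %s", key, conditionMessage(r)),
              call. = FALSE)
      next
    }
    res[[key]] <- r
    rows[[key]] <- data.frame(
      o2_fraction = o2, symbol = r$symbols, g = unname(r$g),
      G_score = unname(r$G), n_samples = r$n_used,
      n_excluded = r$n_excluded, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, class = c("cc_dgsm", "data.frame"), levels_detail = res,
            space = space, d = d)
}

#' @export
print.cc_sens <- function(x, ...) {
  cat(sprintf("DGSM G-scores at o2 = %.3g%% (%d used / %d sampled, %s)\n",
              100 * x$o2, x$n_used, x$n_total,
              if (x$converged) "converged" else "not converged"))
  print(round(x$G, 4))
  invisible(x)
}
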