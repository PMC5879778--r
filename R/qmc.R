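## Quasi-Monte-Carlo parameter-space campaigns: characterisation-curve
## statistics over Sobol-sampled parameter sets, deactivation-parameter
## sweeps, mechanism knockouts, and the initial-condition multistability
## scan.  No RNG anywhere: identical configuration implies identical
## output.

.apply_space_point <- function(p, space, x) {
  do.call(cc_set, c(list(p), as.list(stats::setNames(x, space$symbols))))
}

.binom_ci <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(k, n)$conf.int)
}

#' QMC characterisation campaign
#'
#' Builds the characterisation curve for each Sobol-sampled parameter set
#' in the hypercube and records per set the optimal oxygen, minimum
#' commitment time, convexity factor k and shape class.  The summary
#' reports the fractions of sets with `o2_optimal` in 9-10.5% oxygen,
#' `ct_min` in 3-11 h and `k` in 1-40, each with an exact binomial 95%
#' interval, under two denominators: all sampled sets, and only the sets
#' for which the statistic is defined.
#'
#' @param p a `cc_params` object (baseline values for parameters outside
#'   the space).
#' @param space a `cc_space`; defaults to the P1-P8 hypercube.
#' @param n_sets number of Sobol parameter sets.
#' @param o2_grid oxygen grid per characterisation curve.
#' @param skip Sobol skip.
#' @param t_max commitment horizon (hours).
#' @param refine refine optima below grid resolution?
#' @param points optional explicit matrix of parameter vectors (columns in
#'   `space$symbols` order), overriding Sobol sampling.
#' @return a `cc_campaign`: list with `records` (data frame), `summary`,
#'   `n_sets`, `n_failed`, and the configuration.
#' @export
qmc_campaign <- function(p, space = NULL, n_sets = 500,
                         o2_grid = .default_o2_grid(), skip = 0,
                         t_max = 200, refine = TRUE, points = NULL) {
  if (is.null(space)) space <- parameter_space(p)
  if (is.null(points)) points <- sobol_points(n_sets, space = space,
                                              skip = skip)
  n_sets <- nrow(points)
  rec <- data.frame(set = seq_len(n_sets), o2_optimal = NA_real_,
                    ct_min = NA_real_, k = NA_real_,
                    shape = NA_character_, all_quiescent = FALSE,
                    failed = FALSE)
  for (r in seq_len(n_sets)) {
    q <- try(.apply_space_point(p, space, points[r, ]), silent = TRUE)
    if (inherits(q, "try-error")) { rec$failed[r] <- TRUE; next }
    cv <- try(characterisation_curve(q, o2_grid, t_max, refine = refine),
              silent = TRUE)
    if (inherits(cv, "try-error")) { rec$failed[r] <- TRUE; next }
    if (!any(cv$committed)) { rec$all_quiescent[r] <- TRUE; next }
    rec$o2_optimal[r] <- cv$o2_optimal
    rec$ct_min[r] <- cv$ct_min
    rec$k[r] <- cv$k
    rec$shape[r] <- cv$shape
  }
  smry <- .campaign_summary(rec)
  structure(list(records = cbind(rec,
                                 stats::setNames(as.data.frame(points),
                                                 space$symbols)),
                 summary = smry, n_sets = n_sets,
                 n_failed = sum(rec$failed),
                 space = space, o2_grid = o2_grid, skip = skip,
                 t_max = t_max),
            class = "cc_campaign")
}

.campaign_summary <- function(rec) {
  n_all <- nrow(rec)
  stat <- function(x, lo, hi) {
    def <- !is.na(x)
    hit <- def & x >= lo & x <= hi
    list(n_defined = sum(def), n_in_band = sum(hit),
         frac_of_defined = if (any(def)) sum(hit) / sum(def) else NA_real_,
         frac_of_all = sum(hit) / n_all,
         ci_of_defined = .binom_ci(sum(hit), sum(def)))
  }
  list(n_sets = n_all,
       n_failed = sum(rec$failed),
       n_all_quiescent = sum(rec$all_quiescent),
       o2_optimal_9_105 = stat(rec$o2_optimal, 0.09, 0.105),
       ct_min_3_11 = stat(rec$ct_min, 3, 11),
       k_1_40 = stat(rec$k, 1, 40),
       k_below_1 = stat(rec$k, -Inf, 1 - 1e-12))
}

#' @export
print.cc_campaign <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cc_campaign: %d parameter sets (%d failed, %d all-quiescent)\n",
              s$n_sets, s$n_failed, s$n_all_quiescent))
  pr <- function(lbl, st)
    cat(sprintf("  %-22s %5.1f%% of defined (%d/%d; 95%% CI %.1f-%.1f%%), %5.1f%% of all\n",
                lbl, 100 * st$frac_of_defined, st$n_in_band, st$n_defined,
                100 * st$ci_of_defined[1], 100 * st$ci_of_defined[2],
                100 * st$frac_of_all))
  pr("o2_optimal in 9-10.5%:", s$o2_optimal_9_105)
  pr("ct_min in 3-11 h:", s$ct_min_3_11)
  pr("k in 1-40:", s$k_1_40)
  invisible(x)
}

#' Deactivation-steepness sweep
#'
#' Re-runs the QMC campaign at several values of the ROS deactivation
#' steepness `n_deg`, on identical Sobol parameter sets (paired design),
#' and summarises how the optimal-oxygen distribution, the minimum-CT
#' distribution and the frequency of sub-unit k values respond.
#'
#' @inheritParams qmc_campaign
#' @param ndeg_values values of `n_deg` to sweep.
#' @return a `cc_ndeg_sweep`: named list of campaigns plus a comparison
#'   table.
#' @export
ndeg_sweep <- function(p, space = NULL, n_sets = 500,
                       ndeg_values = c(0.01, 0.1, 1),
                       o2_grid = .default_o2_grid(), skip = 0,
                       t_max = 200) {
  if (is.null(space)) space <- parameter_space(p)
  pts <- sobol_points(n_sets, space = space, skip = skip)
  camps <- list()
  for (v in ndeg_values) {
    q <- cc_set(p, "n_deg" = v)
    camps[[sprintf("n_deg=%g", v)]] <- qmc_campaign(
      q, space, o2_grid = o2_grid, t_max = t_max, points = pts)
  }
  cmp <- do.call(rbind, lapply(seq_along(ndeg_values), function(i) {
    r <- camps[[i]]$records
    s <- camps[[i]]$summary
    data.frame(n_deg = ndeg_values[i],
               median_o2_optimal = stats::median(r$o2_optimal, na.rm = TRUE),
               median_ct_min = stats::median(r$ct_min, na.rm = TRUE),
               frac_k_below_1 = s$k_below_1$frac_of_defined,
               n_defined_k = s$k_below_1$n_defined)
  }))
  structure(list(campaigns = camps, comparison = cmp,
                 ndeg_values = ndeg_values),
            class = "cc_ndeg_sweep")
}

#' ROS activation-threshold sweep
#'
#' Re-runs the QMC campaign at several ROS activation thresholds
#' `[O2]_TH` on the same Sobol parameter sets (paired design) and returns
#' the per-threshold distribution of optimal oxygen.
#'
#' @inheritParams qmc_campaign
#' @param thresholds activation thresholds (oxygen fraction).
#' @return a `cc_o2th_sweep`: named list of campaigns plus a comparison
#'   table of optimal-oxygen medians.
#' @export
o2th_sweep <- function(p, space = NULL, n_sets = 1000,
                       thresholds = c(0.05, 0.10, 0.15),
                       o2_grid = .default_o2_grid(), skip = 0,
                       t_max = 200) {
  if (is.null(space)) space <- parameter_space(p)
  pts <- sobol_points(n_sets, space = space, skip = skip)
  camps <- list()
  for (v in thresholds) {
    q <- cc_set(p, "[O2]_TH" = v)
    camps[[sprintf("o2_th=%g", v)]] <- qmc_campaign(
      q, space, o2_grid = o2_grid, t_max = t_max, points = pts)
  }
  cmp <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    r <- camps[[i]]$records
    data.frame(o2_th = thresholds[i],
               median_o2_optimal = stats::median(r$o2_optimal, na.rm = TRUE),
               n_defined = sum(!is.na(r$o2_optimal)))
  }))
  structure(list(campaigns = camps, comparison = cmp,
                 thresholds = thresholds),
            class = "cc_o2th_sweep")
}

#' Mechanism knockout scenarios
#'
#' Characterisation curves for the four combinations of {Hif2a on/off} x
#' {ROS deactivation on/off} at otherwise nominal parameters.  Hif2a
#' knockout forces `m2 = 0` (no Hif2a protein at any oxygen); ROS knockout
#' forces `DEG = 1` identically (via `n_deg = 0`, which makes the
#' deactivation factor exactly one at all oxygen levels).  Hif1a is active
#' in all scenarios.
#'
#' @inheritParams qmc_campaign
#' @return a `cc_scenarios`: named list of four `cc_curve` objects
#'   (`nominal`, `ros_off`, `hif2a_off`, `both_off`).
#' @export
mechanism_scenarios <- function(p, o2_grid = .default_o2_grid(),
                                t_max = 200) {
  variants <- list(
    nominal = p,
    ros_off = cc_set(p, "n_deg" = 0),
    hif2a_off = cc_set(p, "m2" = 0),
    both_off = cc_set(cc_set(p, "m2" = 0), "n_deg" = 0))
  out <- lapply(variants, characterisation_curve, o2_grid = o2_grid,
                t_max = t_max)
  class(out) <- "cc_scenarios"
  out
}

#' @export
print.cc_scenarios <- function(x, ...) {
  cat("Mechanism knockout scenarios\n")
  for (nm in names(x)) {
    cv <- x[[nm]]
    if (!any(cv$committed)) { cat(sprintf("  %-10s all-quiescent\n", nm)); next }
    cat(sprintf("  %-10s shape %s | ct_min %.3g h at %.3g%% | ct_norm %s | committed range %.3g-%.3g%%\n",
                nm, cv$shape, cv$ct_min, 100 * cv$o2_optimal,
                if (is.na(cv$ct_norm)) "absent"
                else sprintf("%.3g h", cv$ct_norm),
                100 * min(cv$o2[cv$committed]),
                100 * max(cv$o2[cv$committed])))
  }
  invisible(x)
}

## Chunked integration to a steady state; returns list(state, converged).
##
## The hyper-phosphorylated Rb pool (the last species) is a terminal sink
## with no first-order loss, so committed trajectories drift linearly in
## that single coordinate while every other species equilibrates.  Steady
## state is therefore declared when the 12 equilibrating species have
## |d/dt| below tolerance over the trailing window and the sink's influx
## is constant over the same window.
## The settling criterion is mixed absolute/relative: |dy/dt| below
## deriv_tol or below rel_tol * |y| per species.  The relative part matters
## because slowly-degraded species approach steady levels of tens of
## micromolar with decay constants of order 1e-2/h, so a purely absolute
## 1e-6 uM/h criterion would demand thousands of simulated hours while the
## state is already settled to five significant digits.
.steady_state <- function(pv, init, horizon = 400, max_horizon = 2800,
                          deriv_tol = 1e-6, rel_tol = 1e-5, window = 10) {
  t_now <- 0
  y <- unname(init)
  sink <- length(y)
  repeat {
    out <- suppressWarnings(
      deSolve::lsoda(y = y, times = c(0, horizon - window, horizon),
                     func = "cc_derivs", parms = pv,
                     dllname = "hifcycle", initfunc = "cc_initmod",
                     rtol = .solver_defaults$rtol,
                     atol = .solver_defaults$atol, maxsteps = 50000))
    if (attr(out, "istate")[1] < 0)
      return(list(state = NULL, converged = FALSE))
    y_mid <- as.numeric(out[2, -1]); y_end <- as.numeric(out[3, -1])
    d_mid <- .Call(C_cc_derivs, y_mid, as.numeric(pv))
    d_end <- .Call(C_cc_derivs, y_end, as.numeric(pv))
    ok <- function(d, y) all(abs(d[-sink]) <
                               pmax(deriv_tol, rel_tol * abs(y[-sink])))
    settled <- ok(d_mid, y_mid) && ok(d_end, y_end) &&
      abs(d_end[sink] - d_mid[sink]) <
        max(deriv_tol, rel_tol * abs(d_end[sink]))
    if (settled) return(list(state = y_end, converged = TRUE))
    t_now <- t_now + horizon
    y <- y_end
    if (t_now >= max_horizon)
      return(list(state = y_end, converged = FALSE))
  }
}

#' Initial-condition multistability scan
#'
#' For Sobol-sampled parameter sets, initial conditions sampled from the
#' +/-100% hypercube around the default initial conditions, and a grid of
#' oxygen levels, integrates the model to steady state and compares the
#' reached steady-state E2F concentration against the one reached from the
#' default initial conditions.  Reports the fraction of converged
#' simulations that reach a different steady state (relative E2F
#' difference above `diff_tol`).
#'
#' @inheritParams qmc_campaign
#' @param n_param_sets number of Sobol parameter sets.
#' @param n_init_sets number of sampled initial conditions per set.
#' @param o2_levels oxygen tensions scanned.
#' @param horizon integration horizon per convergence attempt (hours).
#' @param deriv_tol steady-state criterion: all |d/dt| below this
#'   (micromolar per hour) sustained over the last 10 h.
#' @param diff_tol relative E2F difference classifying a distinct steady
#'   state.
#' @return a `cc_multistability`: list with `fraction_different`,
#'   `n_compared`, `n_different`, `n_nonconverged`, and the per-case
#'   records.
#' @export
multistability_scan <- function(p, space = NULL, n_param_sets = 100,
                                n_init_sets = 20,
                                o2_levels = seq(0.02, 0.20, by = 0.018),
                                horizon = 400, deriv_tol = 1e-6,
                                diff_tol = 0.01, skip = 0) {
  if (is.null(space)) space <- parameter_space(p)
  ppts <- sobol_points(n_param_sets, space = space, skip = skip)
  init0 <- p$init[.species]
  ic_space <- list(lower = rep(0, length(init0)), upper = 2 * unname(init0))
  ipts <- sobol_points(n_init_sets, dim = length(init0), skip = skip)
  ipts <- sweep(ipts, 2, ic_space$upper, `*`)   # lower bound is zero

  n_diff <- 0L; n_comp <- 0L; n_nc <- 0L; n_failed_sets <- 0L
  recs <- vector("list", n_param_sets)
  for (r in seq_len(n_param_sets)) {
    q <- try(.apply_space_point(p, space, ppts[r, ]), silent = TRUE)
    if (inherits(q, "try-error")) { n_failed_sets <- n_failed_sets + 1L
                                    next }
    row <- data.frame(set = r, o2 = o2_levels, ref_e2f = NA_real_,
                      n_diff = 0L, n_nonconv = 0L)
    for (oi in seq_along(o2_levels)) {
      pv <- .pack_parms(q, o2_levels[oi])
      ref <- .steady_state(pv, init0, horizon = horizon,
                           deriv_tol = deriv_tol)
      if (!ref$converged) { n_nc <- n_nc + n_init_sets
                            row$n_nonconv[oi] <- n_init_sets; next }
      e2f_ref <- ref$state[5L]
      row$ref_e2f[oi] <- e2f_ref
      for (s in seq_len(n_init_sets)) {
        ss <- .steady_state(pv, ipts[s, ], horizon = horizon,
                            deriv_tol = deriv_tol)
        if (!ss$converged) { n_nc <- n_nc + 1L
                             row$n_nonconv[oi] <- row$n_nonconv[oi] + 1L
                             next }
        n_comp <- n_comp + 1L
        rel <- abs(ss$state[5L] - e2f_ref) / max(abs(e2f_ref), 1e-12)
        if (rel > diff_tol) { n_diff <- n_diff + 1L
                              row$n_diff[oi] <- row$n_diff[oi] + 1L }
      }
    }
    recs[[r]] <- row
  }
  structure(list(fraction_different = if (n_comp) n_diff / n_comp else NA,
                 n_compared = n_comp, n_different = n_diff,
                 n_nonconverged = n_nc, n_failed_sets = n_failed_sets,
                 n_total = n_param_sets * n_init_sets * length(o2_levels),
                 records = do.call(rbind, recs),
                 diff_tol = diff_tol, deriv_tol = deriv_tol),
            class = "cc_multistability")
}

#' @export
print.cc_multistability <- function(x, ...) {
  cat(sprintf(
    "multistability scan: %d comparisons, %d distinct steady states (%.2f%%), %d non-converged\n",
    x$n_compared, x$n_different, 100 * x$fraction_different,
    x$n_nonconverged))
  invisible(x)
}
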