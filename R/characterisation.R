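## Characterisation curve: commitment time versus oxygen tension, and the
## derived statistics (CT_min, optimal oxygen, O2_eq, convexity factor k,
## shape class, quiescence boundary, proliferation-rate ratio).

.default_o2_grid <- function() seq(0.005, 0.20, by = 0.0025)

## CT as a plain function of oxygen for a fixed packed-parameter template;
## only the three algebraic inputs depend on oxygen.
.ct_of_o2 <- function(p, t_max, rtol = .solver_defaults$rtol,
                      atol = .solver_defaults$atol) {
  init <- p$init[.species]
  function(o2) .ct_fast(.pack_parms(p, o2), init, t_max, rtol, atol)
}

#' Characterisation curve of commitment time versus oxygen
#'
#' Sweeps commitment time over an oxygen grid and derives the curve
#' statistics: the normoxic commitment time `ct_norm` (at 20% oxygen), the
#' minimum `ct_min` and its refined location `o2_optimal`, the hypoxic
#' equal-CT oxygen `o2_eq` where the commitment time equals `ct_norm`, the
#' convexity factor `k = (ct_norm - ct_min) / (0.20 - o2_eq)`, and the
#' shape class ("U" when `k >= 1`, else "L").  Quiescent grid points are
#' recorded as such (`NA` commitment time), never as numbers; they are
#' excluded from the minimum and from `k`.
#'
#' @param p a `cc_params` object.
#' @param o2_grid ascending oxygen fractions; must contain 0.20 (the
#'   normoxia anchor) and span at least `[0.005, 0.20]` by default.
#' @param t_max commitment horizon per point (hours).
#' @param refine logical; refine `o2_optimal` and `o2_eq` below grid
#'   resolution (bracketed minimisation / root finding).
#' @return a `cc_curve` object: list with `o2`, `ct`, `committed`,
#'   `ct_norm`, `ct_min`, `o2_optimal`, `o2_eq`, `k`, `shape`, the
#'   parameter set and its hash.
#' @export
#' @examples
#' \donttest{
#' cv <- characterisation_curve(cc_parameters(),
#'                              o2_grid = seq(0.005, 0.20, by = 0.005))
#' summary(cv)
#' }
characterisation_curve <- function(p, o2_grid = .default_o2_grid(),
                                   t_max = 200, refine = TRUE) {
  stopifnot(inherits(p, "cc_params"))
  o2_grid <- sort(unique(.check_o2(o2_grid)))
  if (!any(abs(o2_grid - 0.20) < 1e-12))
    stop("o2_grid must include 0.20: ct_norm is anchored at 20% oxygen")
  ctf <- .ct_of_o2(p, t_max)
  ct <- vapply(o2_grid, ctf, numeric(1))
  cv <- structure(list(o2 = o2_grid, ct = ct, committed = !is.na(ct),
                       ct_norm = ct[abs(o2_grid - 0.20) < 1e-12][1],
                       ct_min = NA_real_, o2_optimal = NA_real_,
                       o2_eq = NA_real_, k = NA_real_, shape = NA_character_,
                       t_max = t_max, params = p,
                       parameter_hash = parameter_hash(p)),
                  class = "cc_curve")
  if (any(cv$committed)) {
    opt <- optimal_oxygen(cv, refine = refine)
    cv$o2_optimal <- opt[["o2_optimal"]]
    cv$ct_min <- opt[["ct_min"]]
    cv$o2_eq <- equal_ct_oxygen(cv, refine = refine)
    cv$k <- k_factor(cv)
    cv$shape <- shape_class(cv)
  }
  cv
}

#' Optimal oxygen level and minimum commitment time
#'
#' Locates the oxygen tension minimising commitment time.  The grid argmin
#' is refined by bracketed local minimisation of CT(o2) to 1e-3
#' oxygen-fraction tolerance (quiescent points never participate).
#'
#' @param cv a `cc_curve`.
#' @param refine refine below grid resolution?
#' @return named vector `c(o2_optimal, ct_min)`.
#' @export
optimal_oxygen <- function(cv, refine = TRUE) {
  stopifnot(inherits(cv, "cc_curve"))
  ok <- cv$committed
  if (!any(ok)) stop("no committed point: curve has no optimum")
  i <- which(ok)[which.min(cv$ct[ok])]
  o2_star <- cv$o2[i]
  ct_star <- cv$ct[i]
  if (refine) {
    ## bracket by committed neighbours (fall back to the grid point at the
    ## boundary of the committed range)
    lo <- if (i > 1 && ok[i - 1]) cv$o2[i - 1] else cv$o2[i]
    hi <- if (i < length(cv$o2) && ok[i + 1]) cv$o2[i + 1] else cv$o2[i]
    if (hi > lo) {
      ctf <- .ct_of_o2(cv$params, cv$t_max)
      safe <- function(o2) { v <- ctf(o2); if (is.na(v)) Inf else v }
      opt <- stats::optimize(safe, lower = lo, upper = hi, tol = 1e-3)
      if (is.finite(opt$objective) && opt$objective <= ct_star) {
        o2_star <- opt$minimum
        ct_star <- opt$objective
      }
    }
  }
  c(o2_optimal = o2_star, ct_min = ct_star)
}

#' Equal-commitment-time oxygen on the hypoxic branch
#'
#' Finds the hypoxic oxygen level at which the commitment time equals the
#' normoxic one, i.e. the left-branch crossing CT(o2) = ct_norm with
#' o2 < o2_optimal.  Absent (NA) when no committed hypoxic point reaches
#' ct_norm (flat, L-shaped curves).  The trivial self-crossing at 20% is
#' excluded by construction.
#'
#' @inheritParams optimal_oxygen
#' @return oxygen fraction, or `NA` when no crossing exists.
#' @export
equal_ct_oxygen <- function(cv, refine = TRUE) {
  stopifnot(inherits(cv, "cc_curve"))
  if (is.na(cv$ct_norm)) return(NA_real_)
  opt <- if (is.na(cv$o2_optimal)) optimal_oxygen(cv, refine = FALSE)[1]
         else cv$o2_optimal
  left <- which(cv$committed & cv$o2 < opt)
  if (!length(left)) return(NA_real_)
  if (cv$ct[left[1]] < cv$ct_norm) return(NA_real_)
  ## walk up from the quiescence boundary: the first committed point whose
  ## successor falls below ct_norm brackets the severe-hypoxia crossing
  ## (on a monotone left branch this is the unique crossing; on flat
  ## curves it ignores spurious re-crossings near the optimum)
  i <- NA_integer_; j <- NA_integer_
  for (a in seq_along(left)[-length(left)]) {
    if (cv$ct[left[a]] >= cv$ct_norm && cv$ct[left[a + 1]] < cv$ct_norm) {
      i <- left[a]; j <- left[a + 1]; break
    }
  }
  if (is.na(i)) return(NA_real_)
  if (is.na(j) || !refine) return(cv$o2[i])
  ctf <- .ct_of_o2(cv$params, cv$t_max)
  f <- function(o2) { v <- ctf(o2); (if (is.na(v)) Inf else v) - cv$ct_norm }
  r <- try(stats::uniroot(f, lower = cv$o2[i], upper = cv$o2[j],
                          tol = 1e-5), silent = TRUE)
  if (inherits(r, "try-error")) cv$o2[i] else r$root
}

#' Convexity factor of the characterisation curve
#'
#' `k = (ct_norm - ct_min) / (0.20 - o2_eq)`, in hours per unit oxygen
#' fraction.  Absent whenever `o2_eq` is absent.
#'
#' @inheritParams optimal_oxygen
#' @return numeric k, or `NA`.
#' @export
k_factor <- function(cv) {
  stopifnot(inherits(cv, "cc_curve"))
  if (is.na(cv$o2_eq) || is.na(cv$ct_norm) || is.na(cv$ct_min))
    return(NA_real_)
  (cv$ct_norm - cv$ct_min) / (0.20 - cv$o2_eq)
}

#' Shape class of the characterisation curve
#'
#' "U" when the convexity factor k is present and at least 1 (an interior
#' optimum with a genuine normoxic penalty); "L" otherwise (the curve
#' plateaus toward normoxia).  The boundary k = 1 is classified "U".
#'
#' @inheritParams optimal_oxygen
#' @return `"U"` or `"L"`.
#' @export
shape_class <- function(cv) {
  stopifnot(inherits(cv, "cc_curve"))
  if (!is.na(cv$k) && cv$k >= 1) "U" else "L"
}

#' Quiescence boundary oxygen
#'
#' Bisection (to 1e-4 oxygen-fraction tolerance) for the lowest oxygen at
#' which the cell still commits within the horizon.  Under the nominal
#' calibration the boundary sits near 1.2% oxygen; below it E2F never
#' reaches threshold.
#'
#' @param p a `cc_params` object.
#' @param bracket length-2 oxygen interval whose endpoints straddle the
#'   quiescent/committed outcomes.
#' @param t_max commitment horizon (hours).
#' @param tol bisection tolerance (oxygen fraction).
#' @return the boundary oxygen fraction, or `NA` (with a message) when the
#'   bracket does not straddle.
#' @export
#' @examples
#' \donttest{
#' quiescence_boundary(cc_parameters())  # about 0.012
#' }
quiescence_boundary <- function(p, bracket = c(0.005, 0.05), t_max = 200,
                                tol = 1e-4) {
  stopifnot(inherits(p, "cc_params"), length(bracket) == 2)
  .check_o2(bracket)
  ctf <- .ct_of_o2(p, t_max)
  lo <- min(bracket); hi <- max(bracket)
  q_lo <- is.na(ctf(lo)); q_hi <- is.na(ctf(hi))
  if (!q_lo || q_hi) {
    message(sprintf(
      "bracket [%.4g, %.4g] does not straddle quiescence (low %s, high %s)",
      lo, hi, if (q_lo) "quiescent" else "committed",
      if (q_hi) "quiescent" else "committed"))
    return(NA_real_)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is.na(ctf(mid))) lo <- mid else hi <- mid
  }
  hi
}

#' Hypoxia-to-normoxia proliferation-rate ratio
#'
#' The ratio of inverse commitment times `(1/CT(o2)) / (1/CT(0.20))`, i.e.
#' `ct_norm / ct(o2)`, used as a proxy for the relative proliferation rate
#' under hypoxia.  Quiescence at `o2` yields 0.
#'
#' @param cv a `cc_curve`.
#' @param o2 oxygen tension(s) at which to evaluate (interpolated on the
#'   grid where not a grid point).
#' @return numeric ratio(s); exactly 1 at `o2 = 0.20`.
#' @export
rate_ratio <- function(cv, o2) {
  stopifnot(inherits(cv, "cc_curve"))
  .check_o2(o2)
  if (is.na(cv$ct_norm)) stop("curve is quiescent at normoxia")
  ctf <- .ct_of_o2(cv$params, cv$t_max)
  vapply(o2, function(x) {
    if (abs(x - 0.20) < 1e-12) return(1)
    i <- which(abs(cv$o2 - x) < 1e-12)
    v <- if (length(i)) cv$ct[i[1]] else ctf(x)
    if (is.na(v)) 0 else cv$ct_norm / v
  }, numeric(1))
}

#' @export
print.cc_curve <- function(x, ...) {
  n_c <- sum(x$committed)
  cat(sprintf("cc_curve: %d grid points (%d committed) on [%.3g, %.3g]%% O2\n",
              length(x$o2), n_c, 100 * min(x$o2), 100 * max(x$o2)))
  cat(sprintf("  shape %s | ct_norm %.4g h | ct_min %.4g h at %.3g%% O2 | o2_eq %s | k %s\n",
              x$shape, x$ct_norm, x$ct_min, 100 * x$o2_optimal,
              if (is.na(x$o2_eq)) "absent"
              else sprintf("%.3g%%", 100 * x$o2_eq),
              if (is.na(x$k)) "absent" else sprintf("%.4g", x$k)))
  invisible(x)
}

#' @export
summary.cc_curve <- function(object, ...) {
  out <- list(
    n_points = length(object$o2), n_committed = sum(object$committed),
    ct_norm = object$ct_norm, ct_min = object$ct_min,
    o2_optimal = object$o2_optimal, o2_eq = object$o2_eq,
    k = object$k, shape = object$shape,
    parameter_hash = object$parameter_hash)
  class(out) <- "summary.cc_curve"
  out
}

#' @export
print.summary.cc_curve <- function(x, ...) {
  cat("Characterisation curve summary\n")
  cat(sprintf("  grid points: %d (%d committed)\n", x$n_points,
              x$n_committed))
  cat(sprintf("  CT_norm  : %.4g h (20%% O2)\n", x$ct_norm))
  cat(sprintf("  CT_min   : %.4g h at O2_optimal = %.3g%%\n",
              x$ct_min, 100 * x$o2_optimal))
  cat(sprintf("  O2_eq    : %s\n",
              if (is.na(x$o2_eq)) "absent"
              else sprintf("%.3g%%", 100 * x$o2_eq)))
  cat(sprintf("  k factor : %s -> shape %s\n",
              if (is.na(x$k)) "absent" else sprintf("%.4g h/O2-fraction",
                                                    x$k), x$shape))
  invisible(x)
}
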