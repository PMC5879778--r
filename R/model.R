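## ODE core: parameter packing, right-hand side, trajectory integration and
## commitment-time detection.
##
## At fixed oxygen the three algebraic inputs (Hif1a, Hif2a, DEG) are
## constants, so they are evaluated once in R and passed to the compiled
## right-hand side alongside the kinetic constants.

## Order must match the enum in src/cc_model.c.
.parm_layout <- c(
  "H1", "H2", "DEG",
  "kf3A", "kr3A", "kf3B", "kr3B", "kf6B", "kr6B", "kf12", "kr12", "k8",
  "m9", "k9", "m13", "k13", "kp13",
  "m_E2F", "k_E2F", "m_E2F_RbP", "k_E2F_RbP",
  "m_5cycD", "k_5cycD", "m_cycD_Rb", "k_cycD_Rb",
  "m_RbP", "k_RbP", "m_cycE_RbP", "k_cycE_RbP",
  "m_Rb_nP", "k_Rb_nP",
  "k3a", "k4", "eps",
  "g_Myc", "g_cycD", "g_pp", "g_Rb",
  "d_Myc", "d_H1M", "d_H2M", "d_cycE", "d_E2F", "d_cycD", "d_pp",
  "d_cycD_pp", "d_cycE_pp", "d_Rb", "d_E2F_Rb", "d_RbP",
  "n", "unify", "e2f_th")

.pack_parms <- function(p, o2) {
  k <- p$kinetics
  pv <- numeric(length(.parm_layout))
  names(pv) <- .parm_layout
  pv["H1"] <- hif1a_level(o2, p)
  pv["H2"] <- hif2a_level(o2, p)
  pv["DEG"] <- deg_factor(o2, p)
  kin_slots <- setdiff(.parm_layout, c("H1", "H2", "DEG", "unify", "e2f_th"))
  pv[kin_slots] <- unlist(k[kin_slots])
  pv["unify"] <- as.numeric(isTRUE(p$unify_k_e2f_rbp))
  pv["e2f_th"] <- p$e2f_threshold
  pv
}

#' Right-hand side of the commitment network
#'
#' Evaluates the instantaneous rates of change of the 13 dynamic species at
#' a given state and oxygen tension.  The Hif1a, Hif2a and DEG inputs are
#' computed algebraically from the oxygen tension; every kinetic term of the
#' network (mass-action binding, Hill-type transcription and
#' phosphorylation, basal generation and DEG-scaled degradation) is
#' evaluated literally.
#'
#' @param state named (or ordered) numeric vector of the 13 species
#'   concentrations in micromolar, in the order
#'   `hif1a_myc, hif2a_myc, myc, cycE, e2f, cycD, pp, cycD_pp, cycE_pp,
#'   rb, e2f_rb, rbP, rb_nP`.
#' @param o2 oxygen tension (fraction).
#' @param p a `cc_params` object.
#' @return named numeric vector of rates (micromolar per hour).
#' @export
cc_derivatives <- function(state, o2, p) {
  stopifnot(inherits(p, "cc_params"))
  if (!is.null(names(state))) {
    if (!setequal(names(state), .species))
      stop("state must name exactly the 13 model species")
    state <- state[.species]
  }
  if (length(state) != length(.species))
    stop("state must have ", length(.species), " entries")
  if (any(!is.finite(state)))
    stop("non-finite concentration for species: ",
         paste(.species[!is.finite(state)], collapse = ", "))
  pv <- .pack_parms(p, o2)
  d <- .Call(C_cc_derivs, as.numeric(state), as.numeric(pv))
  names(d) <- .species
  d
}

.solver_defaults <- list(rtol = 1e-8, atol = 1e-10)

#' Integrate the model at fixed oxygen
#'
#' Integrates the 13-species network from an initial state over
#' `[0, t_max]` hours at constant oxygen tension with a stiffness-switching
#' adaptive solver (`deSolve::lsoda`, compiled right-hand side).
#'
#' @param p a `cc_params` object.
#' @param o2 oxygen tension (fraction).
#' @param init optional named initial state; defaults to the parameter
#'   set's initial conditions.
#' @param t_max integration horizon in hours.
#' @param times optional output time grid (must start at 0); defaults to
#'   481 evenly spaced points.
#' @param rtol,atol solver tolerances.
#' @return a `cc_trajectory`: a data frame with `time_h`, the 13 species
#'   columns, and the algebraic inputs `hif1a`, `hif2a`, `deg`; attributes
#'   carry oxygen, parameter hash and solver settings.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_cc(cc_parameters(), o2 = 0.02, t_max = 24)
#' plot(tr)
#' }
simulate_cc <- function(p, o2, init = NULL, t_max = 200, times = NULL,
                        rtol = .solver_defaults$rtol,
                        atol = .solver_defaults$atol) {
  stopifnot(inherits(p, "cc_params"), t_max > 0)
  .check_o2(o2)
  if (is.null(init)) init <- p$init
  init <- init[.species]
  if (is.null(times)) times <- seq(0, t_max, length.out = 481L)
  if (times[1] != 0) stop("output times must start at 0")
  pv <- .pack_parms(p, o2)
  out <- deSolve::lsoda(y = unname(init), times = times, func = "cc_derivs",
                        parms = pv, dllname = "hifcycle",
                        initfunc = "cc_initmod", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integration failed at t = %.4g h (o2 = %.4g)",
                 max(out[, 1]), o2))
  df <- as.data.frame(out)
  names(df) <- c("time_h", .species)
  df$hif1a <- pv[["H1"]]
  df$hif2a <- pv[["H2"]]
  df$deg <- pv[["DEG"]]
  structure(df,
            class = c("cc_trajectory", "data.frame"),
            oxygen = o2, t_max = t_max,
            parameter_hash = parameter_hash(p),
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          steps = unname(attr(out, "istate")[3])))
}

#' Evaluate a trajectory between stored points
#'
#' Monotone-in-time spline evaluation of each species at arbitrary times
#' within the integration window.
#'
#' @param traj a `cc_trajectory`.
#' @param t times (hours) at which to evaluate.
#' @return data frame with `time_h` and the 13 species columns.
#' @export
trajectory_at <- function(traj, t) {
  stopifnot(inherits(traj, "cc_trajectory"))
  if (any(t < 0 | t > max(traj$time_h)))
    stop("requested times outside the integration window")
  out <- data.frame(time_h = t)
  for (s in .species)
    out[[s]] <- stats::spline(traj$time_h, traj[[s]], xout = t,
                              method = "fmm")$y
  out
}

## Fast internal commitment-time kernel operating on a packed parameter
## vector; returns the crossing time in hours or NA if quiescent.
.ct_fast <- function(pv, init, t_max,
                     rtol = .solver_defaults$rtol,
                     atol = .solver_defaults$atol) {
  if (init[5L] >= pv[["e2f_th"]]) return(0)
  ## solver early-return warnings are translated into errors below
  out <- suppressWarnings(
    deSolve::lsodar(y = unname(init), times = c(0, t_max),
                    func = "cc_derivs", parms = pv,
                    dllname = "hifcycle", initfunc = "cc_initmod",
                    rootfunc = "cc_root", nroot = 1L,
                    rtol = rtol, atol = atol))
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integration failed at t = %.4g h", max(out[, 1])))
  tr <- attr(out, "troot")
  if (is.null(tr) || length(tr) == 0 || is.na(tr[1])) NA_real_ else tr[1]
}

#' Commitment time at fixed oxygen
#'
#' Integrates the model and locates the earliest time at which the E2F
#' concentration reaches its commitment threshold, by root detection on the
#' solver's dense solution (not grid inspection).  A run with no crossing
#' within the horizon is classified quiescent.
#'
#' @inheritParams simulate_cc
#' @return a `cc_commitment`: list with `committed` (logical), `ct` (hours,
#'   `NA` when quiescent), `horizon`, `oxygen` and `threshold`.
#' @export
#' @examples
#' \donttest{
#' commitment_time(cc_parameters(), o2 = 0.02)  # about 13.5 h nominally
#' }
commitment_time <- function(p, o2, init = NULL, t_max = 200,
                            rtol = .solver_defaults$rtol,
                            atol = .solver_defaults$atol) {
  stopifnot(inherits(p, "cc_params"), t_max > 0, p$e2f_threshold > 0)
  .check_o2(o2)
  if (is.null(init)) init <- p$init
  init <- init[.species]
  ct <- .ct_fast(.pack_parms(p, o2), init, t_max, rtol, atol)
  structure(list(committed = !is.na(ct), ct = ct, horizon = t_max,
                 oxygen = o2, threshold = p$e2f_threshold),
            class = "cc_commitment")
}

#' @export
print.cc_commitment <- function(x, ...) {
  if (x$committed)
    cat(sprintf("committed: E2F reached %.3g uM at CT = %.4g h (o2 = %.3g%%)\n",
                x$threshold, x$ct, 100 * x$oxygen))
  else
    cat(sprintf("quiescent: E2F below %.3g uM over %.4g h (o2 = %.3g%%)\n",
                x$threshold, x$horizon, 100 * x$oxygen))
  invisible(x)
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat(sprintf("cc_trajectory: %d time points over [0, %.4g] h at o2 = %.3g%%\n",
              nrow(x), max(x$time_h), 100 * attr(x, "oxygen")))
  cat(sprintf("  final E2F: %.4g uM; parameter hash %s\n",
              x$e2f[nrow(x)], substr(attr(x, "parameter_hash"), 1, 8)))
  invisible(x)
}
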