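## Algebraic oxygen-response submodels: Hif1a, Hif2a and the ROS
## deactivation multiplier.  Oxygen is a gas-phase fraction throughout
## (0.02 = 2%); conversion to percent happens only at interfaces.

.check_o2 <- function(o2) {
  if (!is.numeric(o2) || any(!is.finite(o2)))
    stop("oxygen tension must be finite numeric", call. = FALSE)
  if (any(o2 < 0 | o2 > 0.21))
    stop("oxygen tension must lie in [0, 0.21] (fraction; 0.02 = 2%)",
         call. = FALSE)
  o2
}

#' HIF oxygen-response curves
#'
#' Exponential oxygen-response models for the two HIF isoforms.  Each level
#' is `m * exp(b * (1 - |p - o2| / t))`: it peaks at `o2 = p` with value
#' `m * exp(b)` and decays exponentially and symmetrically on both sides,
#' with `t` setting the decay scale (the normalization oxygen level).  Under
#' the nominal calibration Hif1a peaks at 5 uM at 0.5% oxygen and is
#' negligible above 10%, while Hif2a peaks at 5% oxygen and remains
#' detectable at 20%.
#'
#' @param o2 oxygen tension(s), as gas-phase fraction in \[0, 0.21\].
#' @param p a `cc_params` object.
#' @return concentration(s) in micromolar, same length as `o2`.
#' @export
#' @examples
#' p <- cc_parameters()
#' hif1a_level(0.005, p)   # peak, 5 uM
#' hif2a_level(0.05, p)    # Hif2a peak
hif1a_level <- function(o2, p) {
  stopifnot(inherits(p, "cc_params"))
  .check_o2(o2)
  h <- p$hif
  h$m1 * exp(h$b1 * (1 - abs(h$p1 - o2) / h$t1))
}

#' @rdname hif1a_level
#' @export
hif2a_level <- function(o2, p) {
  stopifnot(inherits(p, "cc_params"))
  .check_o2(o2)
  h <- p$hif
  h$m2 * exp(h$b2 * (1 - abs(h$p2 - o2) / h$t2))
}

#' ROS-mediated protein deactivation factor
#'
#' Multiplicative acceleration of all basal protein loss above the
#' activation threshold: `exp(n_deg * (o2 - o2_th) / o2_th)` for
#' `o2 > o2_th` and exactly 1 below it (the unique continuous completion).
#' It models oxidative stress under high oxygen: beyond the threshold,
#' superoxide production is taken to exceed the cell's anti-oxidant
#' capacity and degrade/deactivate proteins generically.
#'
#' @inheritParams hif1a_level
#' @return dimensionless multiplier(s) >= 1.
#' @export
#' @examples
#' deg_factor(0.20, cc_parameters())  # exp(1) under the nominal setting
deg_factor <- function(o2, p) {
  stopifnot(inherits(p, "cc_params"))
  .check_o2(o2)
  r <- p$ros
  ifelse(o2 > r$o2_th, exp(r$n_deg * (o2 - r$o2_th) / r$o2_th), 1)
}
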