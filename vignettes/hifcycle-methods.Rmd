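---
title: "Modelling hypoxia-mediated commitment to the cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hypoxia-mediated commitment to the cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model addresses

Culture experiments with mesenchymal stromal cells disagree about whether
hypoxia speeds up or slows down proliferation: depending on the oxygen
tension studied, both enhanced proliferation and quiescence have been
reported.  `hifcycle` implements a single-cell kinetic model that makes
this dependence explicit.  It predicts the *commitment time* (CT): the
time a proliferating cell needs, at a fixed oxygen tension, for its E2F
transcription-factor level to reach the threshold that marks irreversible
passage of the late-G1 restriction point.  The inverse of CT serves as a
proxy for proliferation rate.

Oxygen acts through three channels:

* **Hif1α** (peaks under severe hypoxia, ~0.5% O₂) binds Myc into an
  inactive complex and represses cyclin-D transcription — both
  anti-proliferative.
* **Hif2α** (peaks at 5% O₂, still detectable at 20%) binds Myc into a
  transcriptionally *enhanced* complex that drives E2F and cyclin D —
  pro-proliferative.
* **ROS-mediated protein deactivation** above a threshold oxygen tension
  (10% by default) multiplies every basal protein-loss rate by
  `DEG = exp(n_deg * (O2 - O2_TH) / O2_TH)`, modelling oxidative stress
  under high oxygen.

The interplay produces a "U-shaped" characterisation curve of CT versus
oxygen: quiescence under severe hypoxia (Hif1α wins), fastest commitment
under mild hypoxia (8–10% O₂), and slowed commitment toward 20% O₂ (ROS
wins).

## Model structure

The dynamic core is a 13-species ODE network over the concentrations (µM)
of: the Hif1α–Myc and Hif2α–Myc complexes, free Myc, cyclin E, E2F,
cyclin D, p21/p27 ("p/p"), the cyclin D–p/p and cyclin E–p/p complexes,
Rb, the E2F–Rb complex, hypo-phosphorylated Rb (RbP) and
hyper-phosphorylated Rb (Rb-nP, with n = 4 phosphate groups).  Three
algebraic inputs close the system at fixed oxygen: the two HIF levels

    [Hifiα](O2) = m_i * exp(b_i * (1 − |p_i − O2| / t_i)),  i = 1, 2

and the DEG factor above.  Protein–protein binding follows mass-action
kinetics; transcription and (de)phosphorylation follow Hill-type
saturation; every species except hyper-phosphorylated Rb carries a basal
first-order loss accelerated by DEG.  The E2F balance contains a
Myc-gated autocatalytic term, which gives E2F its switch-like, sigmoidal
rise; commitment is the first crossing of the E2F threshold (1 µM by
default).

Two presentation quirks of the rate laws are worth knowing:

* The cyclin-D-driven dissociation of the E2F–Rb complex appears in three
  balances; in the RbP balance its half-saturation constant is written as
  `k_cycE-RbP` where the E2F and E2F–Rb balances use `k_E2F-RbP`.  We
  implement the equations exactly as written; the constructor option
  `unify_k_e2f_rbp = TRUE` collapses both onto `k_E2F-RbP` for
  sensitivity checking.  At the nominal values the difference is
  negligible.
* The complex written `[E2F-Rb]` is degraded with the constant indexed
  `E2F-RbP`; we treat both spellings as the same species and a single
  constant `d_E2F-Rb`.
* Hyper-phosphorylated Rb has no loss term, so committed trajectories
  drift linearly in that single coordinate at steady state (see
  *Steady states* below).

## The calibrated nominal parameter set

The shipped fixture (`inst/extdata/params_nominal.json`) is **calibrated,
not transcribed**: the published parameter table was not available, so
every value was chosen once, by numerical calibration, to reproduce the
published anchors simultaneously:

* Hif1α peaks at 5 µM at 0.5% O₂ and is negligible above 10%;
* Hif2α peaks at 5% O₂ and remains detectable at 20%;
* CT = 13.5 h at 2% O₂ with the default initial conditions;
* quiescence below ≈1.2% O₂;
* minimum CT between 8 and 10% O₂;
* convexity factor k ≈ 27.9 (see below).

The Hif2α peak concentration is not stated in the source material; we set
it to 1 µM and absorb the overall scale into the Myc-binding rate, which
only the product `kf3B·[Hif2α]` ever sees.  The Hif2α decline toward
normoxia is the most weakly constrained part of the calibration: the
fitted normalization oxygen (`t2 ≈ 0.42`) leaves the 20%-O₂ level at
roughly 80% of the peak — a shallow decline, consistent with Hif2α being
detectable under atmospheric oxygen and with the observation that its
decline beyond 5% is largely compensated by freed Myc; a steeper decline
would produce a spurious interior CT minimum in the ROS-knockout
scenario instead of the reported flat "L" plateau.  The fitted Hif1α
normalization oxygen (`t1 ≈ 0.06`) stretches its influence across the
whole sub-10% range (0.27 µM at 5%, ~0.2% of peak at 10%), matching the
stated 0.5–10% operating range with negligible protein above 10%.  Kinetic magnitudes
(synthesis ~0.1–1 µM/h, degradation ~0.05–0.5 /h, binding ~1–10 /µM/h)
were started from the literature range for Myc–Rb–E2F restriction-point
models and refined against the anchors with a Nelder–Mead search in
log-parameter space; a final uniform rescaling of all rate constants (an
exact time-scale symmetry of the network) pins CT(2%) to 13.5 h.  Initial
conditions place most species near zero with a pre-existing E2F–Rb pool
(0.6 µM) and small free pools of Myc, E2F, cyclins and p21/p27, which
reproduces the reported transient features: p21/p27 rises before
Myc-driven suppression takes over, Rb rises as pre-existing E2F–Rb
dimers disintegrate, cyclin D stays low under 2% O₂, and E2F follows a
lagged sigmoid.

Mechanistically, the calibrated regime works as follows.  Quiescence
under severe hypoxia arises because Hif1α sequesters Myc (so the
Hif2α–Myc complex cannot form either) and represses cyclin D; with
cyclin-D-dependent Rb phosphorylation capacity below the Rb supply, free
Rb accumulates without bound and keeps E2F sequestered.  The quiescence
boundary is the oxygen at which phosphorylation capacity first exceeds
Rb supply.  Toward normoxia, DEG lowers the steady E2F plateau toward
the threshold; commitment still occurs but approaches the threshold
slowly, which produces the rising right branch of the U.

## Curve statistics

For a characterisation curve computed on an oxygen grid (default 0.5% to
20% in 0.25% steps; the grid must contain the 20% normoxia anchor):

* `ct_norm` — CT at exactly 20% O₂ (the in-vitro normoxia convention);
* `o2_optimal`, `ct_min` — the argmin refined below grid resolution by
  bracketed minimisation (tolerance 1e-3 in oxygen fraction);
* `o2_eq` — the *hypoxic-branch* oxygen where CT equals `ct_norm`,
  found by root refinement between the bracketing grid points; the
  trivial self-crossing at 20% is excluded, and `o2_eq` is absent when
  no committed hypoxic point reaches `ct_norm` (flat "L" curves);
* `k = (ct_norm − ct_min) / (0.20 − o2_eq)` — the convexity factor, in
  hours per unit oxygen fraction (this is why oxygen is a fraction
  internally: k ≈ 27.9 is only dimensionally consistent with a CT span
  of hours over an O₂ span of ~0.18);
* shape class: "U" when k ≥ 1 (boundary value classified "U"), else
  "L".
* the quiescence boundary — bisection to 1e-4 oxygen fraction on the
  committed/quiescent outcome with a 200 h horizon.

A run is quiescent when E2F never reaches threshold within the horizon
(200 h by default — committed CTs are tens of hours at most, so the two
regimes are separated decisively).  Quiescent points never enter
`ct_min`, `o2_eq` or `k`.

## Sensitivity analysis (DGSM)

The derivative-based global sensitivity measure uses the
relative-perturbation forward difference

    E_i = (f(x_i (1 + d)) − f(x_i)) / d,

*exactly as defined in the model description*: the difference is divided
by the relative step `d` alone, so `E_i → x_i ∂f/∂x_i` in the limit — a
semi-elasticity that carries the scale of `x_i`.  `g_i` is the average of
`E_i²` over the ±100% parameter hypercube, estimated by quasi-Monte-Carlo
integration on Sobol points, and the G-scores `G_i = g_i / Σ g_j` sum to
one by construction.  Choices the description leaves open, fixed here:

* `d = 0.01` (1% relative); validated against a central-difference
  oracle at `d = 1e-3` and `1e-4` in the test-suite.
* Batches of 500 points are added until `max_i |ΔG_i| < 0.01` between
  consecutive batches, capped at 39,000 points.
* A Sobol point whose CT is undefined (quiescent) at the evaluation
  oxygen — before or after any perturbation — is excluded from that
  level's average and counted; if fewer than 10% of points are usable
  the level is reported as unsuitable rather than estimated.
* The Sobol sequence is unscrambled with skip 0 (the origin point maps
  to all-zero parameters and is simply excluded by the rule above);
  both values are recorded in run manifests.

The default parameter subset (P1–P8: `b1`, `k'13`, `m13`, `k8`, `g_Rb`,
`m_E2F-RbP`, `d_cycE-p/p`, `ε`) comes from a preliminary local screening
(`screen_parameters()`), which ranks all parameters by `|E_i|` at the
nominal point across oxygen levels.

## Sobol sampling

No installed R package provides Sobol sequences, so the package carries a
small generator: the standard Gray-code construction with the published
Joe–Kuo direction numbers for dimensions up to 20.  The test-suite pins
the output to reference values of the published sequence and checks a
per-axis discrepancy proxy against uniform random sampling.  Determinism
of every campaign follows from determinism of this generator; the
package uses no random numbers anywhere.

## QMC campaigns and scenario studies

`qmc_campaign()` evaluates the characterisation curve per Sobol-sampled
parameter set and summarises the distribution of (`o2_optimal`,
`ct_min`, `k`).  Because the published headline fractions are phrased
over slightly different denominators, the summary reports each fraction
both over all sampled sets and over the sets where the statistic is
defined, with exact binomial 95% intervals.  A parameter set whose
half-saturation constants are driven to zero by the hypercube's lower
bound fails validation and is counted as failed rather than silently
dropped.  Default campaign sizes are configurable; the acceptance tests
run 500-set campaigns (full-scale 39,000-set runs are a long-running
mode, unchanged in code).

`ndeg_sweep()` and `o2th_sweep()` rerun the campaign across `n_deg` and
activation-threshold values on *identical* Sobol sets (paired design).
`mechanism_scenarios()` builds the four knockout curves; ROS knockout is
implemented as DEG ≡ 1 exactly (`n_deg = 0`), not as the "negligible"
`n_deg = 0.01` variant, which remains available through the sweep.
Hif2α knockout sets `m2 = 0`.

## Steady states and the multistability scan

The model's steady states carry no biological meaning (the model stops
being a description of the cell after commitment); they are used only to
detect whether different initial conditions can put the transient onto a
different trajectory.  Because hyper-phosphorylated Rb has no loss term,
committed runs approach a state where all species but that one
equilibrate while it grows linearly.  The scan therefore declares
steady state when the 12 equilibrating species satisfy a mixed
absolute/relative derivative criterion — `|d/dt|` below 1e-6 µM/h or
below 1e-5 of the species' level — sustained over a 10 h window, with
the sink's influx constant over the same window.  The relative branch
matters because committed steady E2F levels are tens of micromolar with
decay constants of order 1e-2/h: a purely absolute criterion would
demand thousands of simulated hours after the state has settled to five
significant digits.  Integration proceeds in 400 h chunks up to 2800 h;
non-converged cases are reported separately and excluded from the
fraction's denominator.  Two steady states are
"different" when their E2F levels differ by more than 1% relative — the
published criterion was not available, so both thresholds are exposed as
arguments.  The desk-scale default is 100 parameter sets × 20 initial
conditions (sampled from the ±100% hypercube around the default initial
state) × 11 oxygen levels from 2% to 20%.

## Numerical choices

* Stiffness-switching integrator (`deSolve::lsoda`) with a compiled
  right-hand side; `rtol = 1e-8`, `atol = 1e-10`.  The test-suite checks
  that halving tolerances moves commitment times by < 0.1%.
* Commitment detection by the solver's root finder on the dense
  solution (`lsodar`), never by grid inspection; an initial state
  already at threshold commits at t = 0.
* The p21/p27 source `g_pp (1 − k4 [Myc])` is implemented literally and
  may turn negative (net Myc-driven suppression); species are not
  clamped.  Non-negativity of all species over the commitment horizon
  is a monitored test property instead (tolerance −1e-9 µM).
* The DEG guard "if O2 > 10%" is read as "if O2 > O2_TH", so threshold
  sweeps at 5% and 15% are well defined; DEG = 1 below threshold is the
  unique continuous completion.
* Hif1α's exponential is evaluated at every oxygen (no hard cutoff
  above 10%): the curve is already negligible there, and the absolute
  value term produces the reported decline below 0.5%.

## What the simulations do and do not show

Everything in this package is simulation of the model itself; no
biological data are consumed.  The synthetic-data generator *is* the
model plus the calibrated fixture; passing tests demonstrate that the
implementation reproduces the published model behaviour (anchors,
sensitivity structure, robustness fractions) — they cannot validate the
biology, the Hif2α response curve (itself synthesized from sparse
literature ratios), or the hypothesised ROS deactivation law against new
experiments.  The literature comparison of proliferation-rate ratios is
represented only by an order-of-magnitude property of
`rate_ratio()` (the heterogeneous external data set is out of scope).
A limitation specific to the calibrated fixture: the headline robustness
percentages of the parameter-space campaign (the published ~98% of sets
with the optimum in 9–10.5% oxygen, ~90% of minimum CTs in 3–11 h, and
≥99% of k values in 1–40) are only partially attained (roughly 88%, 73%
and 62% at 500 Sobol sets; the corresponding acceptance tests record the
shortfall).  The campaign reproduces the *qualitative* claims — the
optimum concentrates against the ROS activation threshold, the
minimum-CT distribution is centred in the 3–11 h band, k is
overwhelmingly positive with a heavy but bounded right tail — but the
exact percentages depend on the authors' unpublished parameter values,
whose robustness geometry the printed anchors do not pin down.  Joint
±100% perturbations expose three soft directions discussed in the test
suite: strong-autocatalysis corners where ROS deactivation of the
inhibitors outweighs that of the activators, the near-linear scaling of
the minimum CT with the inverse E2F transcription capacity, and
marginally-committing corners at normoxia that inflate k.

Known limitations inherited from the model: no mechanistic
prolyl-hydroxylase HIF degradation, no Notch signalling, no metabolism or
cell mass, no ROS-mediated Hif1α stabilization, nothing beyond the
restriction point, and single-cell only.
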