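---
title: "Control-based continuation of a genetic toggle switch: models, controllers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-based continuation of a genetic toggle switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A bistable gene circuit such as the LacI/TetR toggle switch has an
equilibrium curve — steady-state TetR expression against the inducer
IPTG — with three branches inside a hysteresis window: two stable, one
unstable, joined at a pair of saddle-node (fold) bifurcations. Open-loop
experiments can only ever visit the stable branches: the unstable branch
repels trajectories, and with it goes the most informative part of the
curve. The usual workaround is to fit a model to stable-branch data and
read the bifurcation structure off the model, inheriting every modeling
and identification error.

Control-based continuation (CBC) sidesteps the model. An external
feedback controller (in a real experiment: microscopy measurement of a
fluorescent reporter, actuation by inducer concentration in the medium)
stabilizes the circuit around a reference output level. When the control
input *is* the bifurcation parameter, a control signal that merely
settles to a constant is automatically *noninvasive*: the constant
residual input does not distort the equilibrium structure, it only
shifts the abscissa. Each settled experiment therefore yields one point
`(TetR_ss, IPTG_ss)` of the *open-loop* equilibrium curve — including
points on the unstable branch, which the controller has made attracting.

`togglecbc` implements this pipeline in silico: the toggle switch plant
(deterministic ODE and chemical-Langevin SDE), the model-based reference
continuation, the two controllers, the CBC loop, and parameter
estimation from the collected points.

## The plant

Six states: two mRNAs, two proteins (a.u.), two intracellular inducer
concentrations. Transcription of each gene is repressed by the opposing
protein through a decreasing Hill function
`h(x, θ, η) = 1/(1 + (x/θ)^η)`; each repressor is antagonized by its
inducer (aTc sequesters TetR, IPTG sequesters LacI), which enters as an
inner Hill factor on the effective repressor level. Translation and
first-order degradation/dilution close the four biochemical equations;
the inducers exchange linearly across the membrane, with distinct influx
and efflux rate constants (the influx constant applies when the external
concentration exceeds the internal one).

`toggle_params()` carries the nominal constants. A reading note on the
Hill-threshold groups: we adopt the source-model convention that TetR
(modulated by aTc, thresholds `thetaTetR`, `thetaaTc`) regulates LacI
production, and LacI (modulated by IPTG, thresholds `thetaLacI`,
`thetaIPTG`) regulates TetR production. Units follow the nominal table:
proteins and mRNAs in a.u., aTc in ng/mL, IPTG in mM, rates per minute;
aTc is held at 25 ng/mL throughout.

The stochastic plant is the chemical Langevin equation over the eight
pseudoreactions (transcription, translation, degradation of each mRNA
and protein): drift `S a(X)`, diffusion `S diag(√a(X)) dW` with eight
independent Wiener increments, integrated by Euler–Maruyama. Numerical
choices, made once:

* step `dt = 0.1` min — small against the fastest kinetic timescale
  (mRNA half-life ≈ 5 min) while cheap enough for hours-long protocols;
* negative excursions are clamped to zero after each step (the scheme
  is not positivity-preserving); the clamp count is reported and a
  warning is raised if it grows pathological;
* the inducer states are noise-free (no pseudoreactions act on them)
  and are propagated by the same deterministic Euler update.

The deterministic plant integrates with `deSolve` adaptive stepping
(`rtol = atol = 1e-8`) between 5-min samples — the sampling period is
the realistic imaging/actuation interval of a microfluidics platform
and is used consistently by the simulators, the identification data and
the CBC loop.

## The reference curve

`continue_equilibria()` produces the model-based diagram that CBC
results are judged against: pseudo-arclength predictor–corrector
continuation with an analytic Jacobian, adaptive step halving on
corrector failure, and eigenvalue-based stability classification.
Design choices where the method leaves freedom:

* continuation runs on the 4-state biochemical subsystem with internal
  inducers pinned to the external values — exact at equilibrium, and it
  removes the two neutral exchange directions from the corrector;
* arclength is measured in scaled coordinates (mRNAs/50 a.u.,
  proteins/1000 a.u., IPTG/0.25 mM) so predictor steps are balanced;
  initial step 0.01, minimum 1e-5, maximum 0.05 in those units;
* the curve starts from the (unique, low-TetR) equilibrium at IPTG = 0
  and is continued toward increasing IPTG.

Folds are flagged where the tangent's IPTG component changes sign and
refined by bisection on the slope of the analytic single-valued inverse
IPTG(TetR) to |ΔIPTG| < 1e-5. At the nominal constants the diagram has
exactly two folds, near (0.237 mM, 789 a.u.) and (0.383 mM, 154 a.u.),
bounding the unstable branch.

Two deliberately independent cross-checks guard this module: at
equilibrium the model collapses to a scalar fixed-point map in TetR, so
exhaustive bracketing of that map enumerates *all* equilibria at a given
IPTG without any continuation machinery; and the analytic inverse
IPTG(TetR) must reproduce the continued curve pointwise. Both are
enforced in the test suite (root counts and TetR values on an IPTG
grid; relative agreement 1e-6 for the inverse).

## The controllers

**Proportional.** `u = clamp(Kp (TetR* − TetR), [0, 1] mM)`, evaluated
at each 5-min sample and held constant over the interval. The gain is
selected by linearizing the plant at an unstable equilibrium, closing
the IPTG channel through the control law, and bisecting for the
smallest gain that moves the leading eigenvalue into the left half
plane (`tune_kp()`); the linearization uses the influx exchange rate,
the side the controller actually drives from when TetR falls. The
protocol gain 0.0016 mM/a.u. stabilizes every mid-branch
equilibrium of the nominal diagram with comfortable margin (closed-loop
leading eigenvalue ≈ −0.01/min), and `tune_kp()` returns minima below
it. A P controller leaves a nonzero steady-state error — harmless here,
because the collected pair is read at the *achieved* steady state, not
at the reference.

**MPC.** Three stages, mirroring practice in external gene-expression
control:

1. *Identification* (`identify_lti()`): the stochastic plant is excited
   with random aTc/IPTG pulses (default: 40 h, durations 60–240 min on
   the 5-min grid, amplitudes uniform over 0–50 ng/mL and 0–1 mM —
   amplitude ranges and durations are our design choice, stated here
   and in the config defaults). A multivariable ARX predictor (two
   output lags, least squares, data centered on the training means) is
   realized in block observer form, which *is* a discrete innovation
   model `x(k+1) = Ad x + Bd u + Kd e`, `y = Cd x + e` with `D = 0`;
   continuous-time matrices follow by matrix logarithm. Model order
   defaults to 4 (two lags of the two outputs), selected by held-out
   fit; prediction-error least squares is used in place of a strict
   subspace algorithm — the simple linear model is the point, not the
   estimator. Typical fit: ~97% (LacI) / ~95% (TetR) on held-out pulse
   data.
2. *Kalman prediction* (`kalman_predict()`): the innovation form is its
   own one-interval-ahead Kalman predictor; measured LacI and TetR
   correct the state through `Kd` every 5 min. The predictor state is
   initialized from the first measurement under a constant-history
   assumption (a zero initial state would start predictions at the
   training mean and charge the first samples with spurious error).
3. *Optimization* (`mpc_step()`): cost `J = Σ_{k=1..N} (N−k+1) e(i+k)²`
   over a candidate input held constant across the horizon (horizon
   N = 12, i.e. 1 h — beyond the dominant plant time constant of
   ~60 min). The feasible set is the actuation bounds intersected with
   a relative band `[u(1−γ), u(1+γ)]` around the previous registered
   steady-state input (γ = 0.3 for 30-point runs; the band is taken
   relative, reading the band parameter as a percentage). The
   constrained scalar problem is solved by a seeded real-coded genetic
   algorithm (population 40, 30 generations), as in the experimental
   protocol; a dense grid search over the same cost is the test oracle.
   Holding the candidate constant over the horizon keeps the
   optimization one-dimensional and matches the constant-over-band
   constraint. The error-increment-penalized variant of the cost is
   intentionally not implemented: the band constraint replaces it.

## The CBC loop

`run_cbc()` implements the protocol: set a reference, compute the
control action, hold it for 5 min, re-measure, repeat until steady,
average, step the reference. Defaults reproduce the main experiments:
30 references linearly spaced from 1800 a.u. (P; 1200 for MPC, whose
steady-state error is near zero so the reference range equals the
explored range) down to 0; fixed dwell of 9 h 55 min per reference; the
steady state recorded as the mean of the last 12 samples (1 h) of each
signal; plant state carried over between references. The alternative
`detect` mode fits a least-squares line to the last 12 samples of the
error and control signals after a 3-h minimum dwell and advances when
both slopes are below tolerance — defaults 0.5 a.u./sample and 1e-4
mM/sample for the deterministic plant, 5× larger under process noise
(the tolerances are user-set by nature; these values are our stated
choice). The initial plant state is the IPTG = 0 equilibrium.

30 points × 9 h 55 min gives 297.5 h ≈ 298 h of simulated experiment —
the cost that motivates the detect mode, which cuts the total to
~140–165 h in our stochastic runs.

`cbc_fold_demo()` runs the identical loop on the saddle-node normal
form `x' = μ + u − x²`, where noninvasiveness is a two-line argument:
at steady state `x_ss² = μ + u_ss` exactly, so each collected pair sits
on the open-loop curve at the shifted parameter `μ̃ = μ + u_ss`; and the
proportional closed loop at the unstable root `−√μ` has slope
`2√μ − Kp`, so any `Kp > 2√μ` stabilizes it. Both identities are
asserted numerically in the tests.

`check_noninvasive()` certifies collected points the hard way:
re-simulate the *uncontrolled* plant from the collected state with the
input frozen at IPTG_ss and require TetR to stay within 2% for 5 h.
This is demanding on the unstable branch, where any residual settling
error grows at up to e^(0.0055 t/min); it passes because the closed
loop contracts the reference-to-reference transient by roughly e^(−6)
over a 595-min dwell.

## Parameter estimation

The steady-state relation inverts analytically: given a target TetR,
its mRNA follows from the translation balance; the mRNA balance fixes
the required Hill repression level v of the LacI arm; inverting the
Hill function gives the required effective LacI; LacI itself follows
from its own arm given TetR and aTc; one final Hill inversion yields
IPTG (`equilibrium_input()`). Candidate parameter sets for which any
step leaves the real positive domain (v outside (0,1), or available
LacI below the required effective level) are *discarded* — returned as
NA and penalized in the cost, not raised as errors — because such sets
cannot place an equilibrium at that TetR at any real IPTG.

`estimation_cost()` sums, over measured points, the squared distance to
the nearest point of the candidate's predicted curve, in normalized
coordinates: IPTG divided by the maximum applied input (1 mM), TetR by
the maximum measured TetR. The normalization of the TetR coordinate is
not canonical; dividing by the maximum measured value makes both
coordinates O(1) and is our documented choice, used consistently for
the stochastic-density diagnostics as well. The predicted curve is
evaluated on a 400-point TetR grid over the measured range and clipped
to the normalized input range [0, 1].

`estimate_parameters()` fits the 14 free parameters (transcription
leakage and rates, translation rates, all Hill thresholds and
coefficients) with the degradation rates pinned at nominal, by a seeded
genetic algorithm over a box of 0.1×–10× nominal (Hill coefficients
[1, 4]), searching rates and thresholds in log10 space. Population 80,
80 generations — the optimizer budget is our choice (no budget is
canonical); it converges well before the cap on this 14-dimensional,
heavily non-identifiable landscape. Non-identifiability is expected and
observed: fitted constants deviate substantially from nominal while the
fitted *curve* matches closely. The scientific check is therefore
structural, `check_bistability()`: continuation on the fitted model
must find exactly two folds. Fits to CBC data (which include
unstable-branch points) recover bistability essentially always in our
seeded runs; fits to open-loop sweep data (`run_sweep()`, which by
construction collects only stable branches, with ascending/descending
level orderings exposing hysteresis) carry no such guarantee — that
contrast is the point of collecting unstable equilibria.

## What the simulations do and do not emulate

The SDE plant reproduces intrinsic reaction noise at chemical-Langevin
fidelity and the 5-min measurement/actuation cadence. It does not
emulate cell growth and division, cell-to-cell variability, spatial
inducer diffusion, chamber flush-out, actuation delay, or measurement
noise from image segmentation. Passing tests therefore show that the
algorithms are correct and robust to process noise of the modeled kind;
they do not bound performance in a live microfluidics experiment, where
the controller margins would be eroded by delays and slower, correlated
disturbances. An optional actuation delay hook is deliberately left out
of the acceptance surface.

Problem sizes used by the test suite and scripts: the full 30-point
deterministic protocols for both controllers; three seeded repetitions
of the stochastic protocol with steady-state detection (the reported
experiments used ten); 40-h identification records; ten seeded
estimation fits. These sizes keep the whole suite in the minutes range
while exercising every pathway at full protocol fidelity.

## Known limitations

* The membrane-exchange switch (influx vs efflux rate) makes the
  vector field non-smooth on the surface `internal = external`; the
  Jacobian uses the rate on the side of the current exchange direction,
  and the gain tuner uses the influx side. Eigenvalues exactly on the
  switching surface are a convention.
* Fold refinement relies on the analytic inverse being single-valued in
  TetR, which holds for this model class but not for arbitrary
  extensions (e.g. added feedback loops).
* The GA is a global heuristic; `estimate_parameters()` is seeded and
  reproducible, but distinct seeds reach distinct near-optimal
  parameter sets (non-identifiability), and occasional poor fits are
  possible at small budgets.
* Periodic-orbit CBC, two-parameter fold tracking and agent-based
  population simulation are out of scope.
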