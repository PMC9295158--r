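# togglecbc

Control-based continuation (CBC) of a genetic toggle switch, in silico.

## What this is for

The LacI/TetR toggle switch — two mutually repressing genes whose
repression is antagonized by the inducers IPTG and aTc — is bistable:
its steady-state TetR expression against IPTG is an S-shaped curve with
two stable branches and an unstable branch between them, bounded by a
pair of saddle-node (fold) bifurcations. Open-loop experiments can only
reach the stable branches, so the bifurcation structure is usually
inferred indirectly from a fitted model, inheriting its uncertainty.

CBC measures the curve directly. An external feedback controller
stabilizes the circuit around a stepped reference output; because the
control input *is* the bifurcation parameter (IPTG), a control signal
that settles to a constant is noninvasive — the constant residual is
just a shift of the parameter axis. Each settled step yields one point
`(TetR_ss, IPTG_ss)` of the *open-loop* equilibrium curve, including
the unstable branch. The principle in one line, on the fold normal form
`x' = mu + u - x^2` with `u = Kp (x_ref - x)`: at steady state
`x_ss^2 = mu + u_ss` exactly, i.e. the collected pair sits on the
uncontrolled curve at the shifted parameter `mu + u_ss`.

The package is aimed at people prototyping synthetic gene circuits or
studying experimental bifurcation analysis: it provides the toggle
plant (deterministic ODE with Hill kinetics `h(x, θ, η) =
1/(1 + (x/θ)^η)` and inducer membrane exchange; chemical-Langevin SDE
over the eight pseudoreactions, Euler–Maruyama integration), a
model-based pseudo-arclength continuation as reference, a proportional
controller with eigenvalue-based gain selection, an MPC stack
(innovation-form LTI identification → Kalman predictor → γ-band
constrained genetic-algorithm optimization), the CBC loop itself, and
steady-state parameter estimation from the collected points via an
analytic equilibrium inverse and nearest-point cost.

## Worked example

```r
library(togglecbc)

p <- toggle_params()                  # nominal constants, aTc = 25 ng/mL

# model-based reference curve
bd <- continue_equilibria(p)
glance(bd)
#> # A tibble: 1 × 6
#>   n_points n_folds bistable IPTG_fold_lo IPTG_fold_hi aTc_ext
#> 1      160       2 TRUE            0.237        0.383      25
attr(bd, "folds")
#> # A tibble: 2 × 2
#>    IPTG  TetR
#> 1 0.383  154.
#> 2 0.237  789.

# CBC with the proportional controller: the 30-point fixed-dwell protocol
res <- run_cbc(p_controller(Kp = 0.0016),
               cbc_config(ref_start = 1800, ref_end = 0, n_points = 30,
                          dwell_mode = "fixed", dwell = 595, plant = "ode"),
               p)
glance(res)
#> # A tibble: 1 × 7
#>   n_points n_converged total_hours controller   plant IPTG_min IPTG_max
#> 1       30          30        298.  p_controller ode          0        1
round(attr(res, "total_hours"), 1)
#> [1] 297.5
```

The 30 collected points overlap the continuation diagram to better than
1% relative TetR, nine of them on the unstable branch — equilibria that
no open-loop protocol can visit. The run simulates 297.5 h (≈ 298 h) of
experiment time: 30 references × 9 h 55 min dwell. Switching
`dwell_mode = "detect"` advances the reference as soon as the error and
control slopes flatten, cutting the stochastic protocol to ~140–165 h
in our seeded runs.

```r
# estimation from the collected points recovers bistability
meas <- measured_points(res$TetR_ss, res$IPTG_ss, provenance = "cbc-p")
est  <- estimate_parameters(meas, seed = 1)
check_bistability(est)
#> [1] TRUE
```

The fitted constants themselves deviate substantially from nominal
(the steady-state curve does not identify all 14 parameters), but the
fitted model reproduces the two folds — and fits to open-loop sweep
data (`run_sweep()`), which contain no unstable-branch points,
generally do not.

`autoplot()` methods exist for diagrams, CBC results, trajectories and
estimation traces; `tidy()`/`glance()` follow broom conventions. A thin
command-line wrapper with subcommands (`simulate`, `continue`, `run`,
`identify`, `estimate`, `sweep`, `fold-demo`) is installed under
`inst/cli/cbc.R`.

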