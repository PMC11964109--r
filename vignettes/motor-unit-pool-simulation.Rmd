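---
title: "Simulating rate-coded motor-unit pools: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rate-coded motor-unit pools: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mupool)
```

## The model

`mupool` simulates a muscle as a pool of `N` parallel motor units (MUs)
driven by one common, force-like neural drive signal `I(t)` (in Newtons, a
convention that makes the drive directly comparable to the forces it
commands). A task supplies two signals on a uniform grid of step `dt`: the
desired force `Fd(t)` and a force–velocity–length (FVL) gain `g(t)` that
collapses the muscle's normalized length and contraction-velocity state into
one multiplicative scaling of force capacity. Everything downstream of the
drive is per-MU: recruitment and rate coding turn `I(t)` into a firing rate
`r_i(t)`; an event generator turns rates into excitation impulses on the
grid; linear third-order twitch dynamics turn impulses into an activation
state; and the muscle force is the strength- and gain-weighted sum
`FM(t) = sum_i fmax_i g(t) abar_i(t)`.

Key structural assumptions, all deliberate simplifications:

* **Identical contractile machinery.** All MUs share one twitch model and
  one FVL state; they differ only in strength `fmax_i`, threshold `delta_i`,
  bandwidth, and maximum rate `rmax_i`. This isolates recruitment/rate-coding
  structure from fibre-type heterogeneity.
* **Deterministic firing.** No synaptic or axonal noise, no firing
  hysteresis, no doublets: a rate trajectory maps reproducibly to one
  impulse train.
* **Idealized feedback.** The optional feedback term is the undelayed,
  unfiltered force error `Fd - FM`, so closed-loop results bound what any
  physiological feedback could achieve rather than model a reflex arc.

### The nine pool variants

Three threshold/rate families are crossed with three maximum-rate schemes.
The threshold families share their first and last thresholds (`delta1`,
`deltaN`) per muscle, which makes pools comparable but fixes one derived
parameter each:

| family | thresholds | rate function | derived |
|---|---|---|---|
| exponential | `delta1 * Rd^((i-1)/(N-1))`, constant bandwidth `Fmax - delta1*Rd` | capped linear | `Rd = deltaN/delta1` |
| strength-matched | bands as wide as each MU's strength, overlapping by `b1` | capped linear | `b1 = 1 - (deltaN-delta1)/(Fmax-fmax_N)` |
| mixed | power-law-plus-linear mixture | logarithmic (leaky integrate-and-fire steady state) | `Rc = (deltaN-c1)/delta1` |

The strength-matched family is a constructed "linearised" reference: with
`Delta_i = fmax_i` and the linear rate function, each MU's steady-state
force contribution rises with slope approximately one in drive, so the
pool's tetanic input–output map is nearly linear (the suite checks
R² ≥ 0.98 over the recruitment range). The exponential and mixed families
are the physiologically motivated shapes. The `rmax` schemes (constant,
linearly decreasing with `rho1 = 0.25`, exponentially decreasing with
`rho2 = 0.05`) impose onion-skin behaviour of decreasing maximum rates for
later-recruited MUs.

One reading decision is worth recording: in the logarithmic rate function
the pool-position scaling is implemented as `Rr^((i/N)^d2)`, by structural
analogy with the mixed threshold function `Rc^(((i-1)/(N-1))^c2)` whose
endpoint identity (`deltaN = delta1*Rc + c1`) only holds with the exponent
grouped that way. The two indexings (`i/N` vs `(i-1)/(N-1)`) are kept
verbatim per formula; for pools of hundreds of MUs the difference is
negligible.

### Muscle parameterizations

Two presets are built in: a tibialis anterior (TA: `N = 400`,
`Fmax = 400` N, `Rf = 100`, thresholds 0.5–200 N, `rmax1 = 25` Hz, twitch
60/70 ms) and a generic shoulder flexor (SF: `N = 200`, `Fmax = 200` N,
`Rf = 10`, thresholds 0.5–190 N, `rmax1 = 50` Hz, twitch 70/80 ms). The SF
represents only the 200 smallest MUs of a larger muscle — its tasks demand
at most a fifth of `Fmax`, so larger units would never recruit — which is
why its `Rf` and `deltaN` describe a partial pool. Shared constants:
`d1 = 0.1` N·s, `d2 = 1.47`, `Rr = 2.4` (logarithmic rate), `c1 = 29.195` N,
`c2 = 1.833` (mixed thresholds), minimum firing rate zero (the logarithmic
family has an implicit zero minimum, and the linear family adopts the same
so the comparison is fair).

## Impulse trains and the discrete-time correction

An MU fires its first impulse at the first grid instant with `r > 0`, and
impulse `j` at the first grid time `t` with `t >= phi_{j-1} + 1/r(t) - C`.
The carried correction `C` estimates, by linear interpolation between the
two grid steps bracketing the threshold crossing, when the impulse would
have fired in continuous time, and subtracts that overshoot from the next
interval. Without it, every interval would round *up* to the grid and a
40 Hz train at `dt = 2` ms would systematically fire slow. The invariant
the suite enforces is |mean recovered rate − r| ≤ `r·dt` for constant rates
of 5–40 Hz over 10 s.

Numerical details chosen here, and why:

* The firing inequality is evaluated with 1 ns of slack: `t = k*dt` and
  `phi + 1/r` each carry floating-point rounding, and for rates whose period
  is an exact multiple of `dt` a one-ULP miss would otherwise delay the
  impulse by a whole step.
* `C` is clamped to `[-dt, dt]`. By construction the interpolated
  continuous firing time lies within one step of the grid firing time;
  values outside that range can only arise from a degenerate interpolation
  denominator under abrupt rate changes, and are truncated rather than
  propagated.
* The correction is computed only when the rate at the preceding step was
  positive (there is no interval to interpolate out of silence), and `C = 0`
  for each first impulse.
* While `r = 0`, `1/r` is treated as infinite: no impulse fires, and the
  pending interval requirement is re-evaluated from the last firing time
  once the rate returns. An impulse may fire in the same step in which the
  rate becomes positive again, if the elapsed time already satisfies the
  inequality — the "first qualifying grid point" rule, applied uniformly.

## Twitch dynamics, calibration and normalization

Activation is a linear cascade of three first-order stages with time
constants `(tau, tau, tau_c)`. This third-order structure produces
realistically shaped single twitches — finite rise, rounded peak,
exponential-tail decay — with exactly two degrees of freedom, which are
calibrated by Nelder–Mead root-finding on the analytic impulse response so
that the unit twitch peaks at the muscle's time-to-peak `Tp` and decays to
half its peak `Thr` later (tolerance: half a grid step each; infeasible
shape requests, e.g. `Thr` far below what a third-order cascade can
realize, raise a calibration error with the achieved timings in the
message). The response is rescaled to unit peak, so one impulse yields one
unit-amplitude twitch.

Integration is exact: the one-step transition matrix `exp(A*dt)` of the
cascade is evaluated in closed form (the matrix is lower triangular; a
series limit covers near-equal time constants), and impulses enter as unit
state jumps at their grid time. Superposition therefore holds to machine
precision, which the suite verifies directly and against an independent
`deSolve` integration. An earlier implementation used a general-purpose
Padé matrix exponential; its ~5e-8 per-entry error was visible against the
ODE oracle, which motivated the closed form.

Two design decisions matter for interpretation:

* **Tetanic normalization uses the steady-state mean, not the peak.** The
  constant `amax_i` is the mean unnormalized activation over the last 1 s
  of a 4 s simulation of firing at `rmax_i` (≥ 20 twitch durations, so the
  transient has died; one value per distinct `rmax`, cached). Normalized
  activation is clipped at 1, absorbing the ripple of the periodic response
  above its mean. The consequence: a fully driven pool averages `Fmax`
  exactly, but poorly fused configurations (low `rmax * Tp`) lose a few
  percent of peak mean force to clipping — visible in the saturation test,
  which uses a well-fused configuration for that reason.
* **No sub-tetanic nonlinear summation.** Real twitch summation is
  nonlinear below fusion; here the pool-level nonlinearity is carried
  entirely by the tetanic normalization and output clipping, keeping the
  per-MU dynamics linear and exactly integrable. The twitch model sits
  behind a single constructor (`calibrate_twitch()`), so a nonlinear
  summation model can replace it without touching the rest of the
  pipeline. Trapezoidal plateau accuracy is the statistic most sensitive
  to this choice.

## Tasks and the synthetic reaching generator

Three generators cover the study conditions:

* `elementary_tasks()`: the six fitting tasks per muscle — isometric,
  concentric and eccentric shapes at two amplitudes (0.3/0.5 `Fmax` for
  the TA, 0.05/0.2 `Fmax` for the SF), 2 s long, with a 1 s parabolic
  force pulse in the first half (second half for eccentric) and ±20 %
  minimum-jerk length excursions for the dynamic shapes.
* `trapezoid_task()`: isometric ramp–hold–ramp test profiles. The
  protocol's ramp timing is not fixed by the experimental sources, so the
  defaults — 5 % `Fmax`/s ramps, 10 s plateau, 1 s lead-in/out — encode
  "slow" and are configurable; plateau statistics are insensitive to the
  exact ramp rate, and the plateau scoring window drops the first second
  of the hold as settling.
* `synthetic_reach_tasks()`: seeded fixtures emulating the *shape class*
  of reaching demands: 1–2 s tasks, desired force as 1–3 raised-cosine
  pulses with overall peaks drawn in [0.05, 0.2] `Fmax` (the first task
  always has two peaks with a deep inter-peak minimum), and `g(t)` derived
  from a ±20 % minimum-jerk length excursion. These are labelled synthetic
  throughout: they reproduce amplitude range, multi-peak structure and
  nonmonotonic gain, but not the joint-dynamics-induced correlation
  between `Fd` and `g`, the asymmetric velocity profiles, or antagonist
  co-variation of real musculoskeletal output. Tests passing on them show
  the pipeline handles low-amplitude, multi-peaked, non-isometric demands;
  they do not validate against recorded reaching data.

The default FVL gain (used when a task supplies length/velocity rather
than `g`): a Gaussian force–length bell `exp(-((l-1)/0.45)^2)` and a Hill
force–velocity branch `(1 - s)/(1 + s/0.25)` on normalized shortening
speed `s = v/vmax` with `vmax = 5` lengths/s, saturating at 1.5 for
lengthening. These are standard textbook forms with conventional
constants; the tasks only require `g` to be a smooth, bounded,
positive gain, and all four constants are user-settable in
`fvl_params()`.

## Controller fitting

Stage 1 fits `(alpha0, alpha1, beta, tau)` of the feedforward map against
the elementary suite with feedback off, minimizing the summed
time-averaged squared error (rectangle rule on the simulation grid, the
same grid the simulator produces — no separate quadrature). The search
space is `alpha0, alpha1 in [-1, 5]`, `beta in [-2, 2]`, integer
`tau in [0, 50]` samples. The optimizer is a real-coded genetic algorithm
(population 40, 60 generations, tournament-of-2 selection, BLX-0.5
crossover, Gaussian mutation at 20 % gene rate with sigma 10 % of range,
2-elite, `tau` by rounding), restarted 3 times from seeded independent
populations, each restart's best polished by a bounded Nelder–Mead search
over the three continuous parameters with `tau` frozen. The hybrid polish
is part of the optimizer design: genetic search locates the basin cheaply
but converges slowly inside it, and at reduced budgets the unpolished GA
leaves enough parameter error to be visible in long-plateau statistics.
Elitism makes the per-generation best non-increasing, which the suite
asserts. All randomness flows from the user seed (restart `r` uses
`seed + r - 1`), so reports are bit-reproducible.

Stage 2 freezes the feedforward map and fits the scalar feedback gain
`gamma`: a coarse scan of [0, 5] seeds three Nelder–Mead searches, and
`gamma = 0` is always kept as a candidate. The scan exists because the
objective is piecewise flat in `gamma` at the scale of single impulse
shifts, so one simplex can stall on a shelf; the zero candidate guarantees
the reported closed-loop objective never exceeds the feedforward baseline.

## Problem sizes used in the checks

The test suite and the acceptance script run the full TA parameterization
(400 MUs, `dt = 2` ms) for everything deterministic — calibration, maps,
train fidelity, plateau simulation — and fit controllers at a reduced
evolutionary budget (population 24, 30 generations, 3 restarts for the
plateau pipeline; population 16, 12 generations for the nine-pool feedback
comparison), with cheap five-MU muscles for the optimizer-contract and
oracle-equivalence tests. These sizes were chosen so the full
verification cycle stays interactive while leaving the study conditions
themselves (muscle parameters, task definitions, error metrics) untouched.

## Known limitations

* No firing variability, hysteresis, derecruitment asymmetry, fatigue or
  fibre-type twitch variation — all outside scope by design.
* Feedback is idealized (no delay, no noise); closed-loop improvements are
  upper bounds, not predictions.
* Sub-tetanic twitch summation is linear (see above).
* The FVL gain is shared across the pool and supplied by the task; there
  is no tendon elasticity or length-state feedback from the contraction
  itself.
* The synthetic reaching fixtures stand in for, and are not, recorded
  musculoskeletal simulation output.
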