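---
title: "Modelling online group polarization as a stock-and-flow system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling online group polarization as a stock-and-flow system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsim)
```

## The model

`gpsim` simulates how extreme opinions form and recede in the online
public opinion field that appears around a public-health emergency. It
is an aggregate system-dynamics model — the opinion-dynamics
counterpart of a compartmental epidemic model — not an agent-based or
network model: populations ("stocks", in persons) change through
rate-valued transfers ("flows", in persons/day), and the group
polarization (GP) risk of a scenario is read off as the peak of the
negative-extreme stock.

Users attending the emergency pass through up to seven opinion states:

* `P`, `N` — hold a positive / negative opinion, do not interact;
* `PI`, `NI` — positive / negative opinion holders who discuss and
  interact;
* `NIN` — formed a negative but non-extreme opinion through
  interaction;
* `NE` — formed a negative **extreme** opinion (the risk indicator);
* `PIP` — kept a positive opinion through interaction and retired
  from the field (terminal).

An `undecided` pool holds users who attend but have not yet formed an
opinion, and cumulative `entered_cum` / `exited_cum` ledgers close the
mass balance: at every step the stocks plus cumulative exits equal
cumulative entries to within 1e-8 relative — the integrator enforces
this and aborts if it is violated.

### Entry and opinion allocation

Of an initial pool of `S0` users, a fraction `lambda1`
(government-response effect) never enters. Of the entrants,
`delay_fraction` are present at `t = 0`; the rest trickle in at
exponential rate `1/entry_time`. Undecided users pick a side by social
comparison at rates (persons/day)

    Sn = U * lambda5 * p_neg      Sp = U * (1 - lambda5) * p_pos

where `lambda5` is the risk propensity of entrants and
`p_neg = N/(P+N)`, `p_pos = P/(P+N)` are the observed camp shares.
When either camp holds fewer than one whole person the shares ramp
linearly back to an even coin flip: a sub-person camp is not
observable to an entrant, and the bare ratio is singular at the empty
origin (its winner-take-all fixed points make the exact solution
ill-conditioned there; the ramp makes the right-hand side continuous
and the integration step-size-robust).

### Transition flows

Eleven named flows move users between states; all rates are in
persons/day.

| flow | path | rate law |
|------|------|----------|
| v1 | P → PI | `P * lambda6 / T_pi` |
| v2 | PI → PIP | `PI * h(t)` (lifecycle) |
| v3 | N → NI | `N * lambda6 / T_ni` |
| v4 | NI → NE | `NI / T_e` |
| v5 | NI → PI | `NI * lambda2 / T_c` |
| v6 | PI → NIN | `PI / T_c` |
| v7 | PI → NE | `PI * lambda4 * min(1, NIN/NE) / (T_c * T_e)` |
| v9 | NI → NIN | `NI * lambda2 / T_ef` |
| v10 | NIN → NE | `NIN * lambda4 / T_e * min(NIN/NE, cap)` |
| v11 | NE → NIN | `NE * lambda3 / T_ef` |

`lambda6` (information uncertainty) gates all interaction: with
`lambda6 = 0` no user ever starts discussing and `PI`, `NI`, `NIN`
and `NE` remain identically zero. `lambda2` (emotional guidance,
always active) moves interacting negatives towards positive (`v5`) or
non-extreme (`v9`) opinions. `lambda4` (coupling with concurrent
events — e.g. lockdown-related life pressure feeding stereotyped
prejudice) drives both escalation flows `v7` and `v10`; with
`lambda4 = 0` the only route into `NE` is `v4`. The described
negative-to-positive post-discussion conversion coincides with `v5`'s
path and rate, so it is implemented as that single flow and the flow
record reports `v8 = 0`.

Two mechanisms deserve comment:

* **Intervention timing.** Heat reduction (traffic limiting) is a
  reaction to visible extremism, so `v11` — and the escalation ratio
  flow `v10`, which depends on the same extreme-vs-non-extreme
  comparison — stay switched off until `NE` first exceeds
  `heat_threshold` (default 1 person). The switch latches: once
  extreme opinions have been observed the measures stay in force.
* **The escalation ratio `NIN/NE`.** Escalation is strongest while
  extreme opinions are rare relative to negative sentiment. The ratio
  is guarded with `epsilon` (default 1e-9 persons) against division by
  zero and capped (`ratio_cap`, default 10) in `v10`, which bounds the
  quadratic term at start-up; in `v7` the ratio enters through
  `min(1, r)`, which in stochastic mode becomes the success
  probability of a Bernoulli gate.

### Lifecycle exits

Attention to any online topic dies out, so every stock is also drained
by a lifecycle exit. A literal proportional-to-elapsed-time exit rate
would empty all stocks within a day; `gpsim` instead uses the linear
hazard `h(t) = t / exit_scale_days` (per day), so departures are
negligible early and dominate late. `PI`'s lifecycle exit is the
`v2` flow into the terminal `PIP` stock; `NE`'s exit keeps an extra
`1/T_ef` factor — extreme opinion holders linger in the field longer,
scaled by the extinction time of extreme opinions.

`exit_scale_days` is the one calibrated constant in the package: it
was fixed once, by scanning for the value at which the packaged
baseline scenario's `NE` peak falls at day 20 (the timing observed in
the case study the baseline reproduces), and frozen at 365 days. It
was not adjusted afterwards against any other quantity.

## Parameters and defaults

The packaged baseline (`baseline_scenario()`) is a COVID-19-era
drug-approval controversy: a modest pool (`S0 = 100` persons) with
weak government response and emotional guidance
(`lambda1 = lambda2 = 0.2`), moderate heat reduction
(`lambda3 = 0.4`), strong event coupling (`lambda4 = 0.9`), risk
propensity `lambda5 = 0.2` and high information uncertainty
(`lambda6 = 0.5`); time constants `T_c = 2`, `T_e = 6`, `T_ef = 7`,
`T_pi = 3`, `T_ni = 1` days; horizon 100 days. Artifact-level
defaults: `delay_fraction = 0.5` of entrants at `t = 0` and a 3-day
mean delayed entry (half the audience arrives with the news cycle,
the rest follows within days — a choice made once as a realistic
arrival pattern), `heat_threshold = 1` person, `epsilon = 1e-9`,
`ratio_cap = 10`, `exit_scale_days = 365`.

## Numerical scheme

Integration is explicit Euler with `dt = 0.025` day. Euler matches
system-dynamics practice and keeps the per-step stochastic gates
well-defined; the step was chosen so that halving it moves every
stock's peak by well under 1% (the sharp sub-day transient of the
small `N` stock is the binding constraint — at `dt = 0.05` it still
moved ~1.5% per halving). Each step, all outflows of a stock are
rescaled proportionally if they would drive it negative within the
step, so stocks land exactly at zero instead of overshooting and mass
is conserved exactly. Peak times are tie-broken to the earliest
attaining time; fractional-decay times are linearly interpolated
between grid points and are `NA` when the level is never reached.

## Mean-field and stochastic modes

The default `meanfield` mode replaces every random gate by its
expectation and is fully deterministic. In `stochastic` mode two gates
are drawn from the seeded RNG each step: the opinion allocation
(multinomial over the whole persons of the undecided pool, which
guarantees the allocation never exceeds the pool) and the `v7`
escalation gate (Bernoulli with probability `min(1, NIN/NE)`). One
seeded generator drives a run; `run_ensemble()` derives child seeds
deterministically from the root seed, so ensembles are reproducible
and any replicate can be re-run in isolation. The ensemble mean
converges to the mean-field trajectory (the test suite checks every
stock to within 5% sup-norm at 1,000 replicates on the baseline).

## What the baseline does and does not emulate

The baseline scenario is a synthetic study condition, not fitted
data: it reproduces the *structure* of an observed controversy — a
single news-driven entry wave, extreme opinions peaking around day 20,
recession by around day 60 — under exact conservation of a fixed user
pool. Real opinion fields are open systems (users are recruited into
the topic as it trends, so observed engagement counts can exceed any
initial pool), have network structure, and carry measurement noise.
Passing tests therefore demonstrate internal consistency and the
direction and relative size of intervention effects (heat reduction
suppresses and hastens the extreme-opinion peak; removing event
coupling collapses it; emotional guidance barely moves it), not
absolute head-counts for any real event.

## Problem sizes used by the test suite

Property tests run 8–30 randomized configurations at a 20-day horizon
with `dt = 0.1`; the calibration and sensitivity checks run the full
100-day baseline and three 9–10-point one-at-a-time sweeps at the
default step; the ensemble check uses 1,000 replicates recorded
daily. These sizes were chosen to exercise every mechanism at full
resolution while keeping a complete run of the suite in the
few-minutes range.

## A worked run

```{r}
traj <- run_gp(baseline_scenario())
glance(traj)
autoplot(traj)
```

## Known limitations

* Aggregate stocks only: no user-level heterogeneity, no social-graph
  topology, no opinion-value continuum (bounded-confidence dynamics
  are out of scope).
* The closed user pool bounds every stock by the entrant total; the
  model predicts shapes, timings and relative intervention effects
  rather than absolute audience sizes.
* The lifecycle exit hazard is a modelling device with one calibrated
  scale, not an empirically estimated survival curve.
* Explicit Euler is first-order; pathological configurations (time
  constants far below the step) are handled by clamping but resolved
  only to step accuracy.
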