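---
title: "The bombusim colony model: structure, reconstruction and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bombusim colony model: structure, reconstruction and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bombusim)
```

`bombusim` simulates one season of a single *Bombus terrestris* colony with a
system of constant-lag delay differential equations, and layers lethal and
sublethal pesticide-exposure scenarios on top of it. This vignette is the
package's account of the science: the model and its assumptions, the parts
that published sources pin down versus the parts this package had to commit
to, the numerical choices, and what the simulations can and cannot say about
real colonies.

## The model

The colony is described by twelve state variables — in-nest nectar `N` (ml)
and pollen `P` (g), adult workers `W`, two worker and two male larval
substages, three gyne larval substages, and cumulative adult males `M` and
gynes `G` — plus three bookkeeping integrals `Phi_w, Phi_m, Phi_g` of the
per-larva mortality rate and a cumulative worker-emergence counter. Time is
measured in days from the first day of spring; the simulation runs from first
worker emergence (`t0 = 22`) to the start of winter (`T_W = 120`, when hive
functions cease).

**Development is a fixed delay, survival a carried integral.** Stage
durations are fixed (worker 4+6+3+9 = 22 days egg to adult; male 4+8+3+11 =
26; gyne 4+5+4+4+13 = 30), so every developmental flux is a lagged evaluation
of the *effective laying rate* `b*_k(t)` discounted by the mortality its
cohort accumulated while it was a larva. For workers:

* inflow into the first larval substage: `b*_W(t − 4)`;
* substage transfer: `b*_W(t − 10) · exp[Phi_w(t − 6) − Phi_w(t)]`;
* pupation: `b*_W(t − 13) · exp[Phi_w(t − 9) − Phi_w(t)]`;
* adult emergence: `b*_W(t − 22) · exp[Phi_w(t − 18) − Phi_w(t − 9)]`.

Because `dPhi/dt = mu_L(t)`, the exponential of a `Phi` difference is exactly
the survival of that cohort over that age window, whatever the time course of
`mu_L` was. Eggs are not an explicit compartment; oophagy acts on the laying
rate, and egg-stage losses other than oophagy are not modelled. All lags are
derived from the stage-duration table (`stage_schedule()`, `caste_lags()`);
none is a free parameter.

**Resources.** Workers collect `b_NW = 0.6` ml nectar and `b_PW = 0.4` g
pollen per worker-day and consume `mu_NW = 0.35` and `mu_PW = 0.25`; larvae
consume pollen at stage-specific rates `c1..c5` and nectar at twice the pollen
rate (taken in the native ml-per-g units). Consumption terms are throttled by
a saturating factor `g(S) = S/(S + K_store)` so stores cannot run negative.

**Regulation.** Two deficit signals, both of the clamped-relative-shortfall
form `D = clamp((demand − supply)/(demand + eps), 0, 1)` with the published
round-off guard `eps = 0.001`:

* `D_neglect` compares the standing brood `L_tot` to the care capacity `Z·W`
  (`Z = 4` larvae per worker);
* `D_malnut` compares projected consumption (`C` against pollen, `2C` against
  nectar, stocks read as one day's available supply) and combines the two
  channels by their maximum.

Larval ejection uses `mu_L = alpha·D_neglect + beta·D_malnut`
(`alpha = beta = 0.75`); oophagy multiplies every scheduled laying rate by
`1 − D_malnut`. The laying schedule is `b_W = 8.5` eggs/day on `[0, 44)`,
`b_M = 2` and `b_G = 2.6` on `[40, 120)`, so male and gyne larvae first
appear on day 44 and worker and reproductive eggs overlap for four days;
the overlap window is assumed to have no special dynamics.

**Initial conditions.** At `t0 = 22` there are no adult bees; the larval
compartments are pre-filled by integrating the pre-start laying history
(`b*_W ≡ 8.5`, `Phi ≡ 0`), giving 51 first-stage and 25.5 second-stage worker
larvae; stores start at `N0 = 20` ml and `P0 = 10` g.

**Exposure scenarios** compose three channels: an instantaneous cull of a
fraction of adult workers on one day (an LD50 corresponds to fraction 0.5,
applied as an integrator event); persistent multiplicative reductions of the
two collection rates; and reductions of the worker laying rate inside the two
brood windows (eggs laid on days `[0, 13)` are brood 1, emerging from day 22;
days `[13, 22)` are brood 2, emerging from day 35 — so brood-window effects
act on the pre-start history and the initial larvae). The endpoint of every
scenario is cumulative reproductive output `M(T_W) + G(T_W)`.

## What is reconstructed, and how it was calibrated

The sources that parameterise this model publish the rate table, the stage
durations and the verbal description of the regulation terms, but not the
closed functional forms, the larval consumption schedule (only its range,
0.01–0.25 g/day/larva), or the initial stores. Those gaps are filled here as
explicit, config-overridable decisions:

* **Deficit form.** The clamped-relative-shortfall `D` above is the simplest
  form consistent with every published comparison (`C` vs. `P(t)`, `L_tot`
  vs. `Z·W`) and reproduces the published delayed-birth expression exactly.

* **Ejection form.** Two readings of "larvae ejected per worker" are
  implemented. The default (`ejection = "deficit"`) makes the per-larva loss
  rate `alpha·D_neglect + beta·D_malnut`: a fully unattended or unfed brood
  dies at the maximum rate however few workers remain, so *losing workers
  increases brood mortality*. The alternative (`"worker_capped"`) treats
  losses as active ejections with colony-wide fluxes capped at `alpha·W` and
  `beta·W`; under it a cull *reduces* brood mortality (no workers, no one to
  eject), which inverts the role worker scarcity is meant to play in brood
  neglect. The default was chosen for that mechanistic reason.

* **Consumption schedule.** `c = (0.01, 0.13, 0.13, 0.13, 0.25)`: first
  instars at the bottom of the published range, intermediate instars at its
  midpoint, the final gyne instar at the top — consumption ramps with age.

* **Adult reproductives feed from the stores.** `mu_NR = 0.35` ml and
  `mu_PR = 0.35` g per adult male/gyne per day. Males remain in the nest and
  feed, and pre-hibernation gynes gorge, disproportionately on pollen, to
  build overwintering reserves; the elevated pollen rate reflects that.
  Without this term the stores necessarily keep accumulating once the worker
  brood clears (about day 57) — net collection `0.15·W` g/day of pollen then
  exceeds the remaining larval demand under every consumption schedule inside
  the published range — and the stores would peak weeks later than the
  published control season shows. With it, the store peak lands in the
  mid-70s across a wide band of the other choices.

* **Initial stores.** `N0 = 20` ml, `P0 = 10` g: two to three days of initial
  brood demand, so the handover from queen care to the first workers is tight
  but not an artificial crisis.

* **Calibration protocol.** Where a value was not published, candidates were
  scored against the published *control-season* landmarks (worker peak around
  day 60; store peak followed by terminal decline between days 70 and 80;
  reproductives plateauing toward day 100) and the published qualitative
  orderings of the exposure experiments; all values stay inside published
  ranges. The exposure scenarios are then run with no further adjustment.
  The acceptance tests recompute those landmarks; under the defaults the
  control colony peaks at ~144 workers on day 66, the pollen stock peaks on
  day 74, and the season yields ~190 reproductives.

## Numerics

* **Integrator.** Method of steps via `deSolve::dede` (adaptive lsoda with
  interpolated lag access), relative tolerance `1e-8`, absolute `1e-10`,
  maximum step equal to the smallest lag (4 days). Lagged lookups before
  `t0` are answered by the analytic pre-start history, never by the solver.
  Dense output every 0.1 day by default (0.5 day in the heavier test runs);
  landmark days are reported at the output resolution. Derivative
  discontinuities are propagated to second order (`t0` and each schedule
  switch or event time, plus sums of one or two lags) and merged into the
  output mesh.

* **Window ramps.** A laying window that switches on discontinuously makes
  the delayed inflow of an *empty* compartment jump, and an adaptive
  integrator cannot cross such a jump at absolute-tolerance level (the error
  test can never pass; in practice the solver stalled at `t = T* + 12`, the
  male second-substage onset). Window edges therefore carry a centred linear
  ramp of width `switch_ramp = 0.01` day (~15 minutes): integral-preserving,
  biologically invisible, and it restores a continuous right-hand side.
  Setting it to 0 restores sharp half-open windows.

* **Store limiter.** `g(S) = S/(S + K_store)` with `K_store = 0.5` (g or ml).
  The guard scale is deliberately much larger than the round-off constant
  `eps = 0.001` used in the deficit denominators: a 1e-3-wide boundary layer
  would make the system needlessly stiff and defeat fixed-step cross-checks,
  while 0.5 g is negligible against store trajectories in the tens to
  hundreds.

* **Events.** The acute cull is an instantaneous state transform applied by
  the solver's event mechanism inside a single integration (a restart would
  discard the lag history). A cull on the start day transforms the initial
  state directly.

* **Non-negativity.** Every state is non-negative by construction; where a
  compartment drains to exactly zero the interpolated dense output can
  undershoot by solver-tolerance amounts, and the trajectory clamps such
  excursions (anything beyond `1e-4` is treated as an integration failure).

* **Fast path.** The production right-hand side is a specialised closure
  (parameters hoisted to locals, precomputed lag-offset maps, one history
  lookup per unique offset); `run_scenario(reference_rhs = TRUE)` runs the
  documented building-block assembly instead, and the test suite pins the
  two against each other on full trajectories (agreement ~1e-9). A 120-day
  season integrates in about 1.5 s.

* **Verification.** Three independent routes: a discrete-day cohort
  bookkeeping oracle must match cumulative emergences to <0.5% when
  mortality and resource feedback are disabled; forced constant larval
  mortality must reproduce the closed-form survival
  `exp(−m · larval duration)` per caste; and a self-contained fixed-step
  Euler method-of-steps implementation (step 0.01 day) must agree with the
  adaptive solution within 1% on every state component. Halving the solver
  tolerances moves the season endpoint by far less than 0.1%.

## What the simulations do and do not show

The model is deterministic and mean-field: it tracks expected cohort sizes,
not individuals, and has no demographic or environmental stochasticity, no
spatial foraging landscape, no weather, no multi-colony interactions, and a
single season (no queen overwintering loop). Parameter values are
species-level literature estimates, not fits to colony time series. The
simulated exposure experiments therefore demonstrate *mechanistic
consequences of the assumed regulation* — e.g. that combined lethal and
sublethal insults decline more than either alone (the acceptance suite
verifies super-additivity on the full combined grid), and that reproductive
output responds monotonically to each stressor level — rather than calibrated
predictions for field colonies.

One structural finding deserves emphasis. In this reconstruction the severity
of an LD50 worker cull *rises into mid-season* (worst around days 45–65) and
only then fades: a colony culled very early loses few absolute workers and
the queen's fixed laying rate replaces them within days, while a mid-season
cull removes many foragers exactly when the reproductive brood must be
provisioned. With the published care ratio (`Z = 4`), laying rate (8.5/day)
and worker mortality (0.05/day), the care capacity `Z·W` exceeds the standing
brood for any workforce above ~27 workers — reached within three days of
first emergence — so no early-cull neglect cascade is possible, and the
acceptance check that encodes "any cull before day 30 is strictly worse than
any cull after day 40" fails under this reconstruction (and under every
variant we examined: both ejection forms, consumption schedules spanning the
published range, initial stores from near-zero to generous, with and without
adult-reproductive feeding). The timing claim it encodes is recovered if
exposure days are counted from the start of the *simulation* (day 22 of
spring) rather than from the first day of spring; the sweep that computes the
full timing curve (`run_sweep(params, "acute-timing")`) makes the shape easy
to inspect either way.

## Known limitations

* The regulation closed forms, the consumption schedule inside its published
  range, adult-reproductive feeding and the initial stores are reconstructions
  calibrated to the published control season (see above); swapping in exact
  published forms, should they become available, only requires replacing the
  functions in `R/regulation.R`.
* Queen resource consumption and queen mortality are not modelled; the queen
  is an implicit, immortal egg source. With zero workers, unattended larvae
  die through the deficit channel, but the queen herself provides no care
  capacity after day 22.
* Adult males and gynes never die or leave within the season; `M` and `G` are
  cumulative emergence counters, and their store consumption persists to
  `T_W`.
* Brood windows are tied to laying days `[0, 13)` and `[13, 22)`; exposures
  that would shift, rather than thin, the broods are out of scope.
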