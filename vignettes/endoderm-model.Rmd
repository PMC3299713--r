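---
title: "A population-based stochastic model of hESC endoderm induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-based stochastic model of hESC endoderm induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(endosim)
```

## The model

`endosim` simulates a population of human embryonic stem cells (hESC)
exposed to endoderm-inducing media, tracking every cell individually through
fixed one-hour steps over a five-day horizon. The model is an agent-based
descendant of the stochastic regime models developed for hematopoietic stem
cells, adapted to embryonic differentiation: no spatial structure, no
cell--cell signalling, and an ectoderm lineage deliberately omitted (hESC
under endoderm induction express little Sox1, so an ectoderm branch would add
parameters without observable consequences).

Each cell carries:

* **A signalling regime**, Omega (active) or A (quiescent). Omega supports
  proliferation and differentiation; in A the cell is fully frozen — it does
  not age, cycle, die, divide or update propensities. Transfer between
  regimes is stochastic and governed by the cell's **affinity** `a`.
* **An affinity `a > 0`**, drawn uniformly on `(0, a_0max]` at initialisation.
  In Omega it decays geometrically, `a <- a / d` per step with `d > 1`; in A
  it is unaltered. When `a` first falls below the threshold `a_min` two
  permanent changes occur: the cell can never re-enter A, and it becomes
  proliferation-competent. The competence latch survives any later parameter
  change.
* **A lifespan**, uniform on `[l_min, l_max]`. Age advances only in Omega;
  exceeding the lifespan kills the cell (dead cells accumulate in a
  cumulative counter, matching how trypan-blue counts accumulate supernatant
  cells).
* **A cell-cycle clock** on `[0, t_cycle)`. Only during G1
  (`cycle_position < t_g1`) can a cell update lineage propensities or
  transfer Omega to A. A competent cell divides when the clock wraps,
  provided it is still inside its **proliferation window** (uniform on
  `(0, w_max]`; beyond it the cell is senescent) and its phenotype is allowed
  to proliferate under the active mechanism. Daughters inherit phenotype,
  stage, propensities and affinity; age, cycle position and the window/clock
  restart (lifespan and window freshly drawn). The model is silent on
  biological plausibility of affinity inheritance; inheriting the mother's
  value is the most conservative choice, since a daughter of a competent
  mother is then also competent.
* **Lineage propensities**, one accumulator per reachable lineage. In each
  G1 step in Omega exactly one lineage is selected with probability
  proportional to `propensity + eps` and incremented by `delta * nprog_i`.
  Crossing the stage threshold (`x_com`, or `x_com2` in stage 2) commits the
  cell irreversibly. Commitment to the mesendoderm intermediate enters
  stage 2: the affinity is redrawn on `(0, a_0max2]`, competence resets and
  the propensities restart over {definitive endoderm, mesoderm}. Terminal
  phenotypes freeze the propensity map forever. If an uncommitted cell
  transfers to A, its propensities collapse to their arithmetic mean
  (instantaneously — the source models describe only "convergence to an
  average"; a gradual relaxation would add a rate constant the data cannot
  constrain).

Transfer probabilities follow the contracts of the predecessor models, whose
exact functional forms are not restated in the embryonic-stem-cell setting.
We use

* Omega to A: `p = min(1, aa * (a / a_0max) * f(N_A))`, attempted only in G1
  and only while `a >= a_min` (stage-2 cells are normalised by `a_0max2`,
  the bound their affinity was redrawn from);
* A to Omega: `q = min(1, (a_min / a) * f(N_Omega))`;
* crowding `f(N) = 1 / (1 + N / n_scale)` of the destination-regime count,
  frozen at the start of each step.

Any replacement must preserve: `p` increasing in `a` and `aa`, zero below
`a_min`, G1-gated; `q` decreasing in `a`; both depending only on the
destination count.

### Mechanism space

Three biological questions span the candidate mechanism space
(`enumerate_mechanisms()`, 2 x 2 x 3 = 12):

1. does an intermediate **mesendoderm** germ layer exist (two-stage
   commitment: hESC to {mesendoderm, visceral endoderm}, then mesendoderm to
   {definitive endoderm, mesoderm}) or do hESC commit directly to
   {definitive endoderm, visceral endoderm, mesoderm};
2. does **mesoderm express CXCR4**;
3. which phenotypes proliferate: all (`A`), endoderm and uncommitted
   (`EU`), or uncommitted only (`U`). "Endoderm" in `EU` means definitive
   endoderm only: the proposed differentiation scheme shows selective
   expansion of the definitive branch, and visceral endoderm is
   extra-embryonic. Mechanism B — mesendoderm present, CXCR4 absent in
   mesoderm, `EU` proliferation — is the mechanism selected by the original
   analysis.

Observables map to phenotypes through `marker_fractions()`: Sox17+ =
visceral + definitive endoderm; CXCR4+ = mesendoderm + definitive endoderm
(+ mesoderm iff the mechanism says so). Marker positivity is
**commitment-gated**: uncommitted cells with high propensity do not count.
This is the simplest reading of a model that ties marker extraction to
germ-layer populations, but it matters: it forces simulated marker fractions
to start at zero on day 0, so any positive background level in measured
data (e.g. flow-cytometry gating spill) becomes an unfittable floor shared
by every mechanism. See "Limitations".

## Parameters

| name | meaning | unit | default |
|---|---|---|---|
| `a_min` | affinity below which A-entry is lost and proliferation unlocked | – | 0.1 |
| `a_0max` | upper bound of the initial affinity draw | – | 1 |
| `a_0max2` | upper bound of the stage-2 affinity redraw | – | 0.5 |
| `x_com`, `x_com2` | commitment thresholds (stage 1 / 2) | – | 1 |
| `d` | per-step affinity decay factor | – | 1.04 |
| `t_g1` | G1 duration | h | 12 |
| `t_cycle` | cell-cycle duration | h | 32 |
| `l_min`, `l_max` | lifespan range | h | 24, 200 |
| `w_max` | proliferation-window bound | h | 72 |
| `aa` | Omega-to-A transfer scale | – | 0.5 |
| `n_scale` | crowding population scale | cells | 1000 |
| `dt` | time step | h | 1 |
| `nprog` | propensity-update magnitudes (me, ve, de, meso, de2, meso2) | – | 6, 4, 4, 4, 6, 8 |

The propensity exploration constant and base increment are tied to the
stage threshold: `eps = delta = 0.01 * x_com` (resp. `x_com2`). Two
consequences are worth spelling out. First, commitment requires on the
order of `100 / nprog_i` selected updates, so the `nprog_i` magnitudes set
the commitment kinetics. Second, the thresholds scale out of the dynamics
entirely — doubling `x_com` doubles increments, exploration and threshold
alike, leaving every selection probability and commitment decision
unchanged. `x_com`/`x_com2` are therefore *structurally insensitive* under
this update rule and are excluded from the default sampling space; the
degrees of freedom they would carry live in `nprog`.

The defaults were fixed once, before any fitting, to reproduce the
qualitative Condition-A (Activin A) phenomenology at nominal values: a
proliferation lag while affinities decay toward `a_min` (t_cycle and t_g1
in the hESC-typical range), roughly linear cumulative death from the
uniform lifespan assignment, stage-1 commitment unfolding over days 2–4,
and an undifferentiated fraction decaying toward ~10 % by day 5. They are
nominal values for sensitivity analysis and centres for the sampling
bounds, not fitted estimates.

## Simulation settings and reproducibility

`sim_settings()` holds the initial population size, the number of replicate
runs, the 120 h horizon and the 24 h observation interval. The engine uses
a self-contained xoshiro256** generator; each replicate run receives an
independent stream derived from the master seed by splitmix64, so results
are bit-reproducible, independent of evaluation order, and *pairable*:
simulations that share a master seed share replicate streams (common random
numbers). The whole trajectory set is a pure function of
(parameters, mechanism, settings, seed).

The original operating scale is 9000 initial cells and 4000 replicate runs,
with 10000 ensemble samples. The package defaults are desk-scale — 1000
cells, 100 runs, 500 samples — which this implementation's compiled core
runs in about a minute and a half; `convergence_study()` reproduces the
two-dimensional convergence analysis up to the full operating point for
users who want it. All fits label their scale in the result's metadata.

## Sensitivity analysis

Because the model is stochastic, local derivative-based sensitivities are
unavailable; sensitivity is instead the histogram distance `S` between the
distributions (over replicate runs) of a day-5 output simulated at nominal
and at 10 %-perturbed parameter values. Bins come from the nominal sample
via the Freedman–Diaconis rule `width = 2 IQR n^(-1/3)` (linear-interpolation
quantiles; other quantile conventions shift the bin count slightly), with
`k = ceiling(range / width)` equal bins spanning the nominal range and two
explicit overflow bins so that perturbed mass outside the nominal range is
never dropped — making `S` exactly twice the total-variation distance
between the binned empirical distributions, bounded by 2. A degenerate
nominal sample (zero IQR) falls back to a single bin spanning the data.
`S` is *not* symmetric in its arguments (bins follow the nominal sample);
the implementation documents and tests this. Nominal and perturbed
simulations share random streams by default, so `S = 0` exactly for
parameters the mechanism never reads. The sensitive/insensitive split uses
the largest gap in the sorted per-parameter sensitivities — the observed
pattern is a clear jump, but no explicit rule accompanies it, so the gap
rule is ours.

## Ensemble fitting and mechanism ranking

Parameter estimation is deliberately not gradient-based or Bayesian: the
biological parameters are "sloppy" (many combinations fit comparably), so
the object of interest is the *ensemble* of acceptable parameter sets.
`fit_ensemble()` draws uniform samples from a hyper-rectangle
(`default_parameter_space()`: one order of magnitude either side of the
nominal value per sensitive parameter, with `d` widened on the `d - 1`
scale and caps where joint invariants demand), simulates each sample, and
scores it with the mean squared marker residual

```
error = (1 / 2T) * sum_days [ (sox17_sim - sox17_obs)^2
                            + (cxcr4_sim - cxcr4_obs)^2 ]
```

on 0–1 fractions, `T` the number of shared observation days (day 0
included where data exist). On this scale the acceptance thresholds used
throughout (0.025, 0.05, 0.1) are dimensionless fraction² quantities.
Growth and cumulative death never enter the fit; they are day-4-normalised
and compared to data only as a *verification score* after fitting, exactly
because the original analysis used differentiation dynamics for estimation
and growth/death for verification. Samples violating a joint parameter
invariant (possible because bounds are independent per dimension) receive
infinite error and are reported as rejected.

`rank_mechanisms()` repeats the fit for all twelve mechanisms on the same
data, reporting each mechanism's minimum error and verification score. No
structure is asserted for the accepted parameter cloud — the original
analysis found no correlation between accepted values and errors, and the
package's tests assert only the acceptance definition.

## The synthetic calibration generator

No machine-readable experimental data exist for the daily time courses, so
`generate_calibration_data()` produces noise-free nominal curves carrying
the documented qualitative features, per condition:

* **Growth** (day-4-normalised live counts): Condition A declines mildly to
  day 3 (proliferation lag) then rises roughly linearly; Condition B puts
  most growth before day 3.
* **Death**: cumulative and linear, equal slopes.
* **Sox17+**: concave quadratic through zero at day 0, peaking at 19 % on
  day 3 (A) and 23 % on day 2 (B) — inside the observed 19–23 % / day 2–3
  window.
* **CXCR4+**: flat plateau (default 0.10) through day 2, a drop at the
  day-3 sample (0.05 for A, 0.03 for B), then a linear rise with slope
  0.12 /day (A) or 0.20 /day (B) — the steeper Condition-B rise and more
  prominent drop mirror the reported contrast between conditions.

The plateau level, drop depth and rise slopes are generator configuration:
the figures they emulate are not machine-readable, so only the qualitative
features above are asserted anywhere, and figure-derived numbers are never
treated as ground truth. Optional Gaussian per-point noise is clipped back
to valid ranges (fractions to [0, 1], death kept nondecreasing and
re-normalised at day 4); no error model is documented for the original
measurements, so plain additive noise is the default assumption.

`generate_ground_truth()` wraps the simulator itself to produce datasets
with a known generating parameter vector for recovery tests, and
`validation_proxy()` converts simulated undifferentiated/mesendoderm
fraction trajectories to fraction-of-maximum curves, the form in which
they are compared with Oct4 and Brachyury qPCR dynamics.

What the generator does *not* emulate: biological replicate scatter,
flow-cytometry gating background (its nominal curves are exact), day-to-day
media-change perturbations, and any correlation structure between
observables. Tests passing against synthetic data therefore demonstrate
that the pipeline recovers what it was shown, not that the biological
conclusions transfer to new measurements.

## Numerical choices

* Fixed-step updating (dt = 1 h), matching the source pseudo-code; no
  continuous-time scheduling.
* Event order within a step, per cell: affinity decay (with competence
  latch), regime transfer, propensity update + commitment check, ageing and
  death, cycle advance and division. Cells entering A mid-step are frozen
  for the remainder of the step; regime counts in the crowding terms are
  frozen at the step start.
* Dead cells are removed by swap-and-pop; daughters join the population at
  the end of the step and are first processed in the following step.
* A population that reaches zero terminates its run early with zero-filled
  remaining observations and a warning.
* Ties and edge cases: the last histogram bin is closed; commitment uses
  `>=` against the threshold; `min(1, .)` caps both transfer probabilities.
* The R reference implementation (`init_population()`, `update_affinity()`,
  `transfer_step()`, `propensity_update()`, `commit_cell()`,
  `death_and_proliferation_step()`) implements the same rules in vectorised
  R; the test suite drives both engines to identical trajectories in
  deterministic limits (death-only, and division-without-death with the
  horizon capped so daughter randomness cannot matter).

## Known limitations

* **The undifferentiated fraction is weakly identified by marker-only
  fitting.** Sox17+ and CXCR4+ fractions constrain `VE + DE` and
  `ME + DE (+ MESO)`, leaving the split of the remainder between hESC and
  (CXCR4-negative) mesoderm nearly free — the model's sloppiness in its
  purest form. Predicted undifferentiated dynamics from a best fit should
  be read with this in mind, and the accepted-ensemble envelope is the more
  honest summary than any single curve.
* **Commitment-gated markers cannot reproduce a positive day-0 background**,
  so a measured pre-induction CXCR4 plateau contributes an identical,
  unfittable residual floor to every mechanism and carries no
  discriminating information here, although the corresponding drop in the
  measured curves was informative in the original analysis.
* The transfer-probability functional forms are contracts, not derived
  physics; conclusions that depend on their precise shape (rather than
  their monotonicity) are outside what this implementation can support.
* Commitment speed is bounded below by the discrete propensity mechanism
  (about `100 / nprog_i` G1 steps), so marker dynamics rising within the
  first few hours are unreachable at any parameter values.
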