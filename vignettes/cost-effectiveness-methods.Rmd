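---
title: "Methods: a calibrated Markov model of breast-reconstruction cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a calibrated Markov model of breast-reconstruction cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Patients enter the model immediately after delayed breast reconstruction
(tissue expander exchange for an implant, an abdominal free flap, or an
omental fat-augmented free flap) and move monthly among five states:

* `POSTOP_UNCOMPLICATED` — the reconstruction is in place and healthy;
* `SALVAGED` — a complication occurred and the reconstruction was rescued;
* `LOSS` — a complication occurred and the reconstruction failed;
* `REVISED` — an elective aesthetic revision was performed;
* `DEAD` — absorbing.

Each month an uncomplicated patient may suffer a complication with
probability `p_complication_monthly`, which resolves to salvage with
probability `p_salvage_given_complication` and to loss with the
complementary probability; may undergo one elective revision inside a
configurable window (default months 7–24, when most aesthetic touch-ups
happen after the reconstruction has settled); and may die at the
life-table's age-specific monthly rate. A patient can experience at most
one complication pathway over the horizon — `SALVAGED`, `LOSS`, and
`REVISED` exit only to `DEAD`. This single-complication simplification is
standard in reconstruction cost-effectiveness models and is shared by all
three arms, so it does not bias the comparisons.

The same transition kernel drives two engines. `run_cohort()` propagates
the state-occupancy vector (deterministic expectations); `run_microsim()`
samples individual trajectories from identical per-cycle probabilities.
Because they share one kernel, microsimulation means converge to the cohort
expectations by construction; the test suite checks agreement within 3
standard errors at 10,000 patients and within 1 SE at 200,000 for one
smoke case.

### Accrual and discounting conventions

The published description leaves the within-cycle conventions open, so the
package fixes and documents its own:

* utilities and recurring costs accrue **at end of cycle** for the state
  occupied after that cycle's transition, discounted by `d^t` with
  `d = (1 + r)^(-1/12)` (twelve cycle factors compound exactly to one year
  at annual rate `r`, default 0.03);
* one-off salvage/loss/revision costs are charged on the entry cycle;
* the index surgery bundle (surgical + materials, anesthesia, hospital
  stay) is charged at cycle 0 undiscounted;
* **no half-cycle correction.** Microsimulation makes the correction moot
  (events are placed at sampled cycles), and the cohort engine deliberately
  mirrors the microsimulation so the two engines are exactly comparable.
* a patient who dies during a cycle accrues nothing for that cycle — the
  death-truncation property asserted in the tests.

### Peri-operative mortality

The life-table monthly death probability is multiplied by
`anesthesia_mortality_multiplier` (default 1.5) only in cycles containing a
surgical event: the whole entering cohort at cycle 1 (index surgery), and
afterwards only the sub-masses transitioning into `SALVAGED` (salvage
surgery) or `REVISED` (revision surgery). A chronic multiplier would
overstate the anesthesia risk, which attaches to procedures, not to states.
Rows are never renormalised — residual probability stays in the current
state — and the kernel is algebraically row-stochastic, which the tests
check to 1e-12 across all cycles.

### Horizons

The base case runs 5 years (60 cycles); a 2-year setting is selectable
(`--horizon=2` in the analysis scripts), reflecting an ambiguity in the
study description, which states both horizons in different places; we
record the discrepancy and default to the 5-year horizon used for the
primary results. A lifetime option caps age at 100 with death probability 1
beyond the life-table range.

## Synthetic inputs and calibration

### What is published and what is not

The study prints per-arm costs (2024 USD), trajectory-level expected
B-QALYs, cohort demographics, and the pairwise incremental results — but
not the per-cycle transition probabilities, the spread of its sensitivity
distributions, the life table, or the value of the recurring "pain
medication" cost it names among the direct costs. The calibration module
replaces those unprinted inputs with synthetic values chosen so the model
reproduces the printed aggregates.

### State utility weights (closed form)

Let `A(a, b) = Σ_{t=a..b} d^t` be the discounted annuity. The uncomplicated
monthly weight solves `w0 · A(1, H) = target`, so a patient who stays
uncomplicated accrues the published no-complication B-QALY *exactly* (to
floating-point precision); this is the `1e-6` reproduction asserted in the
acceptance tests. Salvage and revision trajectories are piecewise: cycles
`1..τ−1` at `w0`, the remainder at the state weight, with `τ` the expected
event cycle under the calibrated geometric event rate (restricted to the
revision window for revisions). Loss trajectories take the loss target
spread over the whole horizon: published loss-trajectory B-QALYs are near
zero (0.03–0.08 over five years), which is only arithmetically consistent
with losses occurring essentially at entry, so the loss weight is
`target_loss / A(1, H)`. All weights are clamped to `[0, 1/12]` — at most
one B-QALY per year of perfect breast-related quality of life — and an
uncomplicated target above `A(1, H)/12` raises an infeasibility error.

Weights are derived once at the base-case horizon and stored on the
strategy; horizon sweeps and probabilistic draws reuse them rather than
re-deriving, because the weights are properties of the health states, not
of the horizon being summed over.

### Why the calibration includes a recurring medication cost

The published one-off costs alone cannot reach the published cost deltas.
Upfront bundles (surgical + materials + anesthesia + hospital stay) are
17,451.77 / 11,933.29 / 5,171.36 USD for O-FAFF, abdominal flap, and
implant. Against the abdominal flap the upfront gap is +5,518.48, yet the
published total delta is −1,410.10 — the abdominal arm must accumulate
about 6,929 USD more downstream. But even if *every* abdominal-flap patient
were salvaged *and* revised, the one-off downstream costs would total only
about 4,494 USD undiscounted. The study explicitly includes post-surgical
pain-medication costs among its direct costs (without printing a value) and
attributes part of the O-FAFF advantage to reduced pain; a recurring
monthly medication cost is therefore the remaining direct-cost channel, and
the calibration assigns it per arm (bounded at 0–300 USD/month) alongside
the event rates. The uncalibrated configuration keeps the documented
default of 0.

### The search

Four published targets constrain the fit: ΔCost and ΔB-QALY for each of
the two comparisons. With three event rates and a medication cost per arm
the problem is under-determined, so a documented prior selects among
solutions: the O-FAFF arm is held at its prior (monthly complication
probability 0.0015, 90% salvage, revision probability 0.005 in the window,
no recurring medication cost — the study reports the lowest complication
and revision burden for this arm), and the two comparator arms' monthly
complication probabilities and medication costs are searched. The solver is
cyclic coordinate descent with a golden-section line search on each
coordinate, minimising the sum of squared relative deviations, evaluated by
the deterministic cohort engine only (microsimulation is reserved for
validation, so the objective is noise-free). Only the arm a coordinate
touches is re-evaluated, so a line-search step costs one cohort run; the
full study calibration converges to residuals below 1e-6 in about two
seconds. The salvage split and revision rates stay at their priors
(implant 50% salvage — implant complications more often end in explantation
— versus 90% for the flaps; revision priors ordered abdominal > implant >
O-FAFF).

The achieved calibration reproduces ΔCost to well within ±100 USD and
ΔB-QALY within ±0.02, and yields the published classification in both
comparisons (an ICER of ≈9,712.63 vs the published 9,712.64, which is the
rounding of 9227/0.95; and dominance over the abdominal flap). A
parameter-recovery property test re-derives known ground-truth rates from
their own simulated targets on 20 random draws.

### Synthetic life table and cohorts

Shipping national vital-statistics tables is unnecessary for a synthetic
stand-in: adult all-cause mortality is well approximated by a Gompertz
curve, so `generate_life_table()` anchors annual female mortality at 0.004
at age 50 (the order of published mid-life female rates) doubling every 8
years, converted to monthly probabilities by
`q_m = 1 − (1 − q_a)^(1/12)`. A CSV hook (`read_life_table()`) accepts real
tables with columns `age,sex,monthly_death_probability`.
`generate_synthetic_cohort()` samples truncated-normal ages on [18, 100]
from the published arm-level means/SDs (49±8, 51±9, 55±9); the engines use
each arm's mean entry age, so arm-level mortality differences are part of
the calibrated comparison.

### What the synthetic module does and does not emulate

It emulates the *structure* of the study's unprinted inputs — stationary
monthly event rates, a single revision window, age-driven mortality — and
is calibrated only to printed aggregates. It does not emulate time-varying
complication hazards (real surgical complications cluster early),
correlation between patient characteristics and risk, repeat complications
or revisions, or the true national life table. Passing tests therefore
demonstrate that the implementation is internally correct and that the
published aggregates are jointly reachable under this structure — not that
the synthetic rates equal the institution's true rates, which are not
identifiable from the published information.

## Sensitivity analyses

**Deterministic.** `one_way_dsa()` re-runs the full pairwise evaluation at
85%/100%/115% of a single input. The default tornado sweeps the
intervention's surgical + materials cost and the time horizon (±15% of 5
years lands on 51 and 69 cycles). The published sensitivity table's own
base-case ratios are not consistent with the published primary results
table, so the deterministic analysis is validated structurally instead: a
zero-width sweep must reproduce the base case bit-for-bit, and dominance
over the abdominal flap must survive every swept level (it does — the
published table shows the same all-dominant row).

**Probabilistic.** Costs are drawn from moment-matched gamma distributions
(`shape = m²/s²`, `scale = s²/m`) and transition proportions from
moment-matched beta distributions (`ν = m(1−m)/s² − 1`), the two families
the study names; utility weights are not sampled, because no utility
distribution is described. Spreads are unprinted, so every varied parameter
takes `sd = 15%` of base, mirroring the deterministic ±15% range, with
per-parameter overrides available. Parameters are sampled independently
(no correlation information is published). Each of the 5000 draws is
evaluated by the deterministic cohort engine so that parameter uncertainty
is not confounded with patient-level noise. Acceptability curves count NMB
ties as cost-effective with probability 0.5 to avoid directional bias. With
these defaults the intervention is cost-effective at USD 50,000/B-QALY in
essentially all draws — consistent with the study's report of 99%, which is
not exactly reproducible without the original spreads.

## Numerical choices

* Strategy comparisons refuse to mix horizons or discount rates.
* Effect differences below `1e-9` B-QALY classify as EQUIVALENT, guarding
  against ICER blow-ups in probabilistic draws.
* ICERs are reported to two decimals in exports; the cost-saving but
  less-effective quadrant carries a ratio plus an explicit label rather
  than a bare (sign-ambiguous) ICER.
* Randomness: one master seed; each patient's uniforms come from a
  substream keyed by `(seed, patient index)` (all seeds kept below 2³¹),
  so microsimulation results are independent of execution order and a
  single patient simulated alone matches the same patient inside the
  vectorised cohort run exactly — asserted in the tests.
* Coordinate-descent line searches use a relative tolerance of `1e-8` of
  each bound width; the cohort engine's occupancy vector is checked to sum
  to 1 within `1e-10` at every cycle.

## Problem sizes

The shipped tests run the published sizes where they matter (10,000-patient
microsimulation, 5000 probabilistic draws, 100,000-draw sampler moment
checks) and smaller, 2-year toy configurations for calibration round-trip
properties, which keeps the full suite under two minutes without weakening
any assertion.

## Known limitations

* Direct payer costs only; indirect/societal costs are out of scope, as in
  the study's base case.
* No extended dominance / efficiency frontier across the three arms
  simultaneously: only the two published pairwise comparisons.
* One complication pathway per patient; no tunnel states beyond the single
  revision window; no semi-Markov sojourn-time effects.
* The calibrated rates are one plausible solution of an under-determined
  inverse problem, selected by the documented priors; they are synthetic
  stand-ins, not estimates of institutional rates.
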