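---
title: "A lifetime Markov cohort model of apixaban versus LMWH/VKA for venous thromboembolism: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apixcea)
```

## The decision problem

Patients with an acute venous thromboembolism (VTE) — deep vein thrombosis
(DVT) or pulmonary embolism (PE) — need anticoagulation to treat the acute
event and prevent recurrence. The package compares, from a UK NHS
perspective and over a lifetime horizon, three strategies for a cohort
entering at the index event (mean age 56.9 years, 58.7% male, 65.8% index
DVT):

* **apixaban for 18 months** — 10 mg BID for 7 days, 5 mg BID to month 6,
  2.5 mg BID to month 18;
* **LMWH/VKA for 6 months** — LMWH bridging with dose-adjusted VKA and INR
  monitoring, then no further treatment;
* **LMWH/VKA for 18 months** — as above with VKA extended to month 18.

Outputs are discounted (3.5%/year) life-years, QALYs and costs by category,
undiscounted lifetime event counts per 1000 patients, and incremental
cost-effectiveness ratios (ICERs), with one-way, probabilistic and
treatment-duration sensitivity analyses.

## Model structure

A Markov cohort steps through 3-month cycles until the cohort is extinct or
reaches a maximum age (default 100; survivors at the cap are moved to death
over the following year, which bounds the cycle count and is negligible at
a 3.5% discount rate). States are: on-treatment and off-treatment (each
split by DVT/PE history), a two-cycle re-treatment tunnel (by course drug
and history), semi-absorbing post-intracranial-bleed and CTEPH states, and
death split by cause (VTE, fatal bleed, other). Each cycle the alive,
non-semi-absorbing cohort faces competing risks of recurrent VTE, major
bleeding, clinically relevant non-major (CRNM) bleeding, non-bleeding
adverse-event discontinuation, CTEPH onset (PE history only) and
other-cause death.

Key structural conventions:

* **Transient events are expected-value pulses.** Recurrent DVT/PE, non-IC
  major bleeds and CRNM bleeds return patients to (or via a tunnel, near)
  their originating state; their costs and time-limited utility decrements
  are booked at incidence. This preserves at most one structural transition
  per cycle.
* **Re-treatment tunnel.** A recurrence triggers a fresh 6-month course —
  of the current drug if on treatment, of LMWH/VKA if off treatment — run
  through the acute (0–3 month) and post-acute (3–6 month) risk schedule
  under the course drug's relative effects, carrying that drug's costs,
  monitoring and disutility. Afterwards patients resume the arm schedule if
  still within the intended duration, else go off treatment.
* **Monotone PE history.** Once a patient has had a PE (index or
  recurrent) they remain in PE-history states and stay at CTEPH risk; a
  recurrent PE moves a DVT-history patient to PE history. A recurrent DVT
  in a PE-history patient is counted as a DVT event (cost, disutility, PTS
  eligibility) without downgrading the history.
* **Severe PTS is a background attribute**, not a state. Under the default
  interpretation the 8.1% five-year cumulative incidence after a DVT is
  converted to a constant per-cycle onset hazard applied for 20 cycles to a
  queue of PTS-eligible mass (entered at the index DVT and refreshed by
  each incident recurrent DVT); prevalence carries a lifelong 0.07 utility
  decrement and an £18 per-cycle cost. The queue and the prevalence pool
  are scaled each cycle by overall survival, an expected-value
  approximation that slightly blurs which individuals die. A literal
  reading of the source table (8.1% *per cycle*) is available via
  `long_term$pts_interpretation = "per_cycle"`.
* **Treatment changes on events** follow the published policy: permanent
  discontinuation after IC bleeds and for 52.7% of non-IC major bleeds
  (the remainder interrupt for 14 days), a 2-day interruption after CRNM
  bleeds, and off-treatment transfer on adverse-event discontinuation.
  Interruptions reduce within-cycle drug cost and treatment disutility but
  not that cycle's risks.

## Hazard arithmetic

All rate/probability conversions assume a constant hazard within the
period: `r = -log(1-p)/t`, `p = 1 - exp(-rt)`. Relative risks are applied
on the hazard scale, `p' = 1 - (1-p)^rr`, which keeps results in [0, 1) for
any positive effect size; at the event rates modelled here this differs
from direct multiplication by under 2%. Competing risks are combined by an
exponential-race allocation: with per-event hazards `r_j`, the total event
probability is `P = 1 - exp(-sum r_j)` and event `j` receives
`P * r_j / sum r_j`, so the effective probabilities and the stay
probability sum to one exactly.

Major and CRNM bleeding hazards rise by a factor 1.97 per decade of age
after month 18 (the trial-informed window needs no adjustment), anchored
at the cohort age at month 18. By default the multiplier applies to on-
and off-treatment bleeding alike; `settings$age_bleeds_off_treatment =
FALSE` restricts it to treatment exposure, a reading that better matches
the published absolute lifetime bleed counts under this package's survival
but is less literal about the source text. Both choices leave the
incremental results almost unchanged.

## Risks and relative effects

The apixaban arm uses the absolute per-cycle risk schedule (trial-derived,
with 95% CIs) directly. Comparator and off-treatment risks apply constant
relative effects to the contemporaneous apixaban schedule: initial-period
LMWH/VKA effects to month 6, extended-VKA effects afterwards, and
extended-placebo effects off treatment. Off-treatment major bleeding uses
the reported absolute annual rate (0.48%) rather than its poorly
identified relative risk. Beyond month 18 — past the trials' horizon — two
extension rules are needed:

* *off treatment*, recurrence follows a schedule of annual probabilities
  by time since cessation (see auxiliary inputs below), with cessation
  approximated by the end of the 18-month trial window for all arms; bleed
  risks continue at the extended-period annual rates under the placebo
  effects;
* *on treatment* (lifelong-duration scenarios only), recurrence continues
  at the mean of the four extended-period per-cycle risks (0.3875%/cycle)
  and bleeds/discontinuation at their extended annual rates.

## Mortality

Background mortality comes from an annual life table (`age, qx_male,
qx_female`), sex-weighted by the cohort's fixed male fraction and rescaled
to the cycle under a constant within-year hazard; age indexes the table by
completed years. Holding the sex mix fixed over the lifetime is an
approximation (male mortality is higher, so the surviving cohort slowly
feminises); its effect on *incremental* results is negligible because it
is common to all arms. Condition-specific excess mortality multiplies the
background hazard: a post-VTE ratio for all alive states, and additional
ratios in the CTEPH and post-IC-bleed states.

## Costs and utilities

Accrual is start-of-cycle, per cycle `k` discounted by `1.035^(-0.25k)`;
half-cycle correction is off by default (`settings$half_cycle_correction`),
matching the era's spreadsheet cohort models, and switches both life-year
and occupancy-based accruals to adjacent-cycle averages when enabled. The
index event's acute cost and 30-day decrement are booked at entry by
default (`settings$include_index_event`); being identical across arms they
cancel from every increment. Drug costs follow the dosing schedule (the
7-day loading/bridging block priced inside the first cycle of each
course); INR monitoring costs £122.18 in the first cycle of each VKA
course and £58.72 per subsequent cycle; LMWH courses carry a one-off
self-injection education cost and per-day administration for the 8% who
cannot self-inject. IC bleeds cost an acute sum plus a post-acute sum over
the first three months, then £672.53 per cycle for life; CTEPH costs an
acute sum then £4182.56 per cycle for life. The post-IC and CTEPH state
utilities (0.33, 0.65) persist from the acute period onward — the source
prints no separate long-term values — so these states are deliberately
harsh on quality of life.

## Parameters, intervals and distributions

Every input ships with its printed mean and 95% CI. Three derivations are
documented rather than printed:

* proportions published with denominators but no interval (the
  recurrent-event type splits; the major-bleed split and the
  discontinuation fraction, for which an effective n of 100 is assumed)
  get normal-approximation CIs from those counts;
* costs printed without intervals (drug prices, monitoring) vary ±30%, the
  range the original sensitivity analysis used for the apixaban price;
* the printed interval for the LMWH/VKA treatment decrement (mean 0.013,
  "0.000–0.0047") is impossible and is read as a misprint: the lower bound
  is kept and the upper bound reconstructed by symmetry (0.026).

For probabilistic analysis each uncertain parameter is assigned a
distribution from its mean and CI — beta for probabilities, fractions and
utilities, gamma for costs, lognormal for relative risks — by moment
matching: the CI width supplies the standard deviation (`(hi-lo)/3.92`; on
the log scale for lognormal) and the analytic mean equals the point value
exactly. Mean preservation implies the lognormal *median* sits below a
right-skewed point estimate; this matters for the very wide extended-VKA
major-bleed interval (see the PSA section). Draws are independent; the
recurrent-event splits are renormalised to the simplex after sampling.

## Auxiliary inputs the source does not print

Two input groups are cited to external studies without printed values.
They ship as clearly flagged assumptions (`source = "assumption"` in
`parameter_table()`), every report logs them, and
`auxiliary_sensitivity()` shows both headline ICERs across their
plausibility ranges:

* **Excess-mortality hazard ratios**: post-VTE 2.0 (long-term
  mortality-rate ratios after VTE cluster around 1.5–3 in cohort studies;
  2.0 also brings the model's absolute discounted life expectancy nearest
  the published value within that band), CTEPH 4.0, post-IC bleed 2.5.
* **Late off-treatment recurrence**: annual probabilities 11%, 5%, 3%, 2%
  for years 0–1, 1–5, 5–10 and beyond since cessation, the pattern of the
  cited ten-year post-cessation cohort (cumulative roughly 11% at 1 year,
  29% at 5, 40% at 10).

## The synthetic life table

`generate_life_table()` is deterministic Gompertz–Makeham mortality,
`q(a) = 1 - exp(-(A + B e^{theta a}))` per sex, with constants calibrated
once (least squares on the life-table expectation) to published UK 2011–13
period life expectancies: 79.0/18.3 years at birth/65 for males, 82.8/20.8
for females. It emulates the *level and age-shape* of modern UK mortality
smoothly; it does not reproduce any specific national release's
year-by-year values (infant and young-adult mortality are smoothed away),
so results feed through the same pipeline a real table would
(`read_life_table()` on an `age,qx_male,qx_female` CSV) but small
deviations from an official table are expected and are one reason the
package targets tolerance-band rather than exact reproduction.

## Probabilistic analysis and its limits

`run_psa()` re-runs all three arms per draw and summarises draws as a
cost-effectiveness acceptability curve: the fraction of draws each arm has
the highest net monetary benefit (`NMB = WTP × QALY − cost`) at each
willingness-to-pay value; dominance handling is implicit in NMB
maximisation. The curve probabilities sum to one at every threshold and
the whole analysis is reproducible from its seed. The probability that
apixaban is *best of the three* at £20,000/QALY is materially lower than
the probability that it beats the 6-month comparator *pairwise* (also
reported, as `p_beats_6m`/`p_beats_18m`): the extended-VKA major-bleed
relative risk's enormous printed interval (1.09–76.40) makes the
apixaban-versus-18-month margin fragile draw by draw. Readers comparing
against published acceptability figures should note which of these two
quantities a sentence refers to.

## Numerical choices

Cohort evolution stops when alive mass falls below 1e-13 (or at the age
cap), tight enough that toy models meet closed forms to 1e-10. Marginal
probabilities are capped at `1 - 1e-12` before hazard transforms so the
forced-death year at the age cap stays finite. Mass conservation is
asserted every cycle at 1e-9 and a violation raises an internal error
rather than propagating. Event splits, policy fractions and occupancy are
plain doubles throughout; no stochastic rounding is involved anywhere in
the deterministic pipeline, so identical arms produce bitwise-identical
traces and exactly zero increments.

## Problem sizes

The packaged analyses use the study's own scales: 3-month cycles to age
100 (about 180 cycles), three arms, 2000 PSA draws. A full deterministic
base case runs in well under a second and the 2000-draw PSA in a few
minutes on one core. The test suite exercises the same code on toy
configurations (single-risk, pulse and two-arm analytic models) whose
closed forms gate the engine at 1e-10, and on a 10^6-draw exponential-race
simulation that validates the competing-risk allocation.

## What the tests do and do not show

Passing tests establish that the arithmetic is right: conversions,
competing-risk allocation, accrual accounting, discounting, distribution
moments, seed-reproducibility, and agreement with closed forms on models
small enough to solve by hand. They do not validate the model against
patient-level outcomes: the synthetic life table is a stand-in for an
official one, the auxiliary hazard ratios and late-recurrence schedule are
literature-shaped assumptions, and the trial-derived inputs inherit the
trials' populations and follow-up. Known limitations shared with the
original model: no memory of multiple recurrences (risks do not rise after
a recurrence), no further VTE or bleeding events after IC bleed or CTEPH,
and treatment changes alter costs and utilities but not subsequent risks.
Limitations specific to this implementation: cessation time for the late
recurrence schedule is approximated by model month 18 in all arms, PTS
bookkeeping is an expected-value queue, and the cohort's sex mix is fixed
over the lifetime.
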