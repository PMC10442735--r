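---
title: "The diabudget model: HbA1c-linked complication risk and budget impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diabudget model: HbA1c-linked complication risk and budget impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabudget)
```

## The question the model answers

A South African private-sector payer considering a digital,
diabetes-nurse-educator supported care program (MyDiaCare) on top of
standard of care wants to know the net financial consequence of adoption:
scenario-with minus scenario-without costs over a five-year horizon, per
year, cumulatively, and per treated patient. `diabudget` implements that
deterministic budget impact analysis (BIA), together with the
patient-level clinical outcome metrics (HbA1c change, treatment-target
attainment, care-plan adherence) used to characterise the program's
observed effect, exercised on synthetic cohorts.

## Model structure

The model is cohort-level, not patient-level. Each scenario is a cohort
characterised by two numbers: mean HbA1c at baseline and at 6 months
(standard of care 9.0% → 8.2%, taken from the South African private-sector
arm of the DISCOVER observational program; MyDiaCare 7.8% → 7.2%, from the
nurse-educator study the clinical pipeline mirrors). HbA1c is assumed
stable beyond 6 months, so:

* **Year 1** spends its first half at the baseline level and its second
  half at the 6-month level; its annual complication incidence is the
  arithmetic mean of the adjusted incidences at the two levels.
* **Years 2–5** use the 6-month level alone, so incidence is constant from
  year 2 onward.

Seven complications carry published annual baseline incidences and 2021
unit costs per event:

```{r complications}
cfg <- default_config()
cfg$complications[, c("name", "complication_class",
                      "baseline_incidence_fraction", "cost_2021_zar")]
```

Risk scaling follows the ADVANCE HbA1c threshold rules: macrovascular
event risk rises 38% per 1% of HbA1c above 7.0%; microvascular risk rises
40% per 1% above 6.5%; below the thresholds risk is flat. The rule is
applied in 0.1% increments, so the multiplier is

$$ m(h) = 1 + r \cdot \frac{\lfloor 10\,\max(0, h - \tau) + 0.5 \rfloor}{10}, $$

with threshold $\tau$ and per-point increment $r$; the excess is snapped
to the nearest 0.1 (ties up). Summing 3.8%/4.0% steps per 0.1% is
algebraically identical to this closed form; the test suite keeps the
step-summing formulation as an independent oracle and checks agreement to
1e−12 on the whole 0.1 grid in [4, 20].

Three reconstruction choices were genuinely open, and we fixed them by
requiring that the model reproduce all published headline figures
simultaneously:

1. **Additive, not geometric, scaling.** "38% per 1%" could compound per
   step. The additive form reproduces the published year-1 totals
   (≈114 / 87 / 27.5 billion ZAR) within ~1%; geometric compounding
   overshoots badly at the standard-of-care baseline (9.0%).
2. **Year-1 half-year averaging.** Using the 6-month level alone for all
   of year 1 underestimates the year-1 figures; averaging the two
   half-years matches them.
3. **Treated population = prevalence + same-year incident cases**
   (371,528 in year 1). This denominator reproduces both the published
   per-patient net impact (≈71,000 ZAR) and the 2%-uptake figure
   (≈528 million ZAR); prevalence alone does not.

The published incidences are treated as threshold-level rates scaled by
each cohort's multiplier. Whether the original authors intended that
reading cannot be settled from the text; it is the only reading we found
that reproduces their outputs.

Adjusted incidences are capped at 1 (they are probabilities); no default
parameterisation reaches the cap. There is no discounting, mortality
attrition, or legacy effect — deliberately, to match the analysis being
reproduced, which applies none.

## Costs and calibrated inputs

Expected events are incidence × treated population; complication cost is
events × 2021 unit cost; monitoring cost is a per-patient annual cost ×
treated population; totals are their sum, and the budget impact is the
element-wise scenario difference. All monetary arithmetic is double
precision; values are rounded to whole ZAR only in report writers.

Two inputs are *calibrated*, not primary, and the parameter audit table
(`parameter_audit()`) flags them:

* **Monitoring costs.** The underlying tariff items (NHRPL fees, market
  research estimates) are not published per item; only the scenario
  totals are: 2.5 billion ZAR without and 3.6 billion with the program
  over the year-1 treated population (the "3.6 million" appearing in one
  printed sentence is inconsistent with the stated 43% increase on 2.5
  billion and is treated as a typo for billion). The packaged per-patient
  costs are those totals divided by 371,528 — ≈6,729 and ≈9,690
  ZAR/patient/year.
* **Medical inflation.** Only source-cost / 2021-cost endpoint pairs are
  published. The packaged annual rates are back-derived from anchor
  pairs: the 2021 rate from the amputation pair (5.0%), the 2020 rate
  from the stroke pair, and a constant 2015–2019 rate from the
  myocardial-infarction pair; the assigned source years are an
  inference from those pairs. `inflate_cost()` compounds over
  `(from_year, to_year]` and reproduces every published 2021 cost within
  0.5% (the anchors exactly).

One rounding wrinkle: the published year-1 *total* reduction appears both
as a rounded "26 billion" (117 − 91, both rounded) and, implicitly, as
27.5 − 1.1 = 26.4 billion from the same results; the model produces
26.58 billion, consistent with the latter. The in-repo acceptance test
compares against the component-consistent 26.4.

## Sensitivity analysis

`one_way_dsa()` varies each parameter to value × (1 ∓ variance) — default
±10% — holding everything else fixed, records the year-1 per-patient net
impact, and sorts by output range (tornado order). The default parameter
set covers the seven unit costs, seven incidences, four cohort HbA1c
levels, year-1 prevalence and the two monitoring costs. HbA1c levels are
varied multiplicatively like every other parameter, under the single
uniform variance. Parameters entering the outcome linearly (unit costs,
incidences, monitoring) produce bars symmetric about the base case;
prevalence produces a flat bar because the per-patient outcome is
population-invariant — both are tested. The named alternative scenarios
are `equal_baseline_scenario()` (standard of care pinned at the program
cohort's 7.8% baseline for both timepoints, isolating the HbA1c *change*)
and `market_share_scenario()` (per-year uptake fractions applied to the
deltas, not to absolute scenario totals — the reading consistent with the
published 2%-uptake figure; default shares 2%…6%).

## Clinical pipeline conventions

* **Timepoint matching**: the measurement nearest the nominal 3/6/9/12
  month timepoint within ±6 weeks; the reporting convention for such
  windows is not stated in the source material, so this rule is the
  package's own and is tested explicitly.
* **Target attainment** is judged on the endpoint value alone
  (`at_most` direction for HbA1c, lipids, blood pressure,
  anthropometrics; `at_least` for HDL); endpoint short of target but
  strictly better than baseline is `improved_not_reached`; the four
  categories partition the cohort.
* **Adherence**: per item, `min(1, performed / expected) × 100` with
  `expected = planned_per_year × followup_months / 12` floored at 1 (a
  test planned at all is due at least once during any ≥6-month
  follow-up); capping at 100% reflects that over-performance earns no
  credit. A patient's overall adherence is the unweighted mean of item
  percentages.
* **HbA1c bands** default to <7.0, 7.0–7.9, 8.0–8.9, ≥9.0 and are
  configurable; a change of ≤ −0.4 percentage points is flagged
  clinically relevant.

## The synthetic cohort generator

The generator emulates the *structure* of the nurse-educator study: 117
patients (8 type 1 / 109 type 2), baseline HbA1c normal with mean 7.8
(SD 1.4) truncated to a plausible range, 6-month change normal with mean
−0.6 (SD 1.3) with the 6-month value floored at 4%, paired-data
availability 79/117, staggered enrollment, 6- or 12-month follow-up, and
care plans whose per-item completion probabilities mirror the reported
pattern (near-complete for laboratory tests and physician/nurse
consultations; partial for dietetic consultations and eye and foot
examinations).

Truncation uses **symmetric acceptance regions**: draws are accepted on
the configured range intersected with its reflection about the target
mean (e.g. baseline on [4.5, 11.1] rather than [4.5, 15]). Naive
one-sided truncation of the 6-month value at 4% would inflate the mean
change by ≈ +0.1 percentage points — patients with low baselines would
reject mostly the negative changes — silently decalibrating the generator
from the very quantity it is supposed to reproduce. Symmetric truncation
preserves the generated means exactly (near-degenerate intervals collapse
to the clamped mean; under the defaults this affects ~1% of patients by
at most 0.1). SDs are mildly shrunk by truncation; the recovery contract
covers the means and the paired fraction.

A `stratified = TRUE` mode draws exact subgroup counts (8 type 1, 79
paired) so tests can pin the study's printed denominators; the default
mode is binomial. Values are reported to 0.1%, as a laboratory would. By
default no correlation between adherence and HbA1c change is induced (the
study reports none); intermediate visits interpolate baseline → 6-month
and later visits hold the 6-month level with 0.3% residual noise, since
only the two endpoint distributions are constrained by the study.

What passing tests on synthetic cohorts do **not** show: anything about
real-data messiness — measurement error correlated with disease severity,
informative missingness (the generator's missingness is independent
Bernoulli), joint distributions across cardiometabolic parameters
(unreported, so sampled independently), or longitudinal glucose dynamics.

## Problem sizes and numerical choices

The full budget model is a few hundred floating-point operations and runs
in well under a second. The test suite uses cohorts of 117 (study scale)
for exactness checks, 40 replicates at study scale for distributional
checks, and a single n = 5,000 cohort for parameter recovery within 3
standard errors; oracle-agreement checks run at 1e−12, engine-vs-brute
force at 1e−6 relative. Excess-HbA1c snapping uses `floor(10x + 0.5 + 1e-9)`
so grid values represented just below a tie still round up.

## Limitations

Cohort-mean risk adjustment ignores the distribution of HbA1c around the
mean (a convex risk function makes this an underestimate for wide
distributions); complications are independent and non-fatal; costs are
per event with no severity mix; the equal-baseline scenario inherits the
comparator's monitoring costs; and the calibrated monitoring inputs carry
the published totals' rounding. These are properties of the analysis
being reproduced as much as of this implementation.
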