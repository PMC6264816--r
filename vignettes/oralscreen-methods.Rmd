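---
title: "Cost-utility modelling of a multi-step oral cancer screening cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility modelling of a multi-step oral cancer screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`oralscreen` re-implements, as a tested and configurable pipeline, the
decision model behind the published cost-utility evaluation of Thailand's
population-based oral precancer screening programme: a Markov cohort of
40-year-olds followed to age 100 in one-year cycles, screened every year
through an ordered cascade of imperfect, imperfectly attended examinations
— mouth self-examination (MSE), visual examination by trained dental nurses
(VETDN), by trained dentists (VETDT) and by oral surgeons (VEOS), with
biopsy confirmation — and compared against opportunistic self-referral
care.  Outcomes are lifetime discounted costs (2016 Thai baht, societal
perspective) and quality-adjusted life years, summarised as an incremental
cost-effectiveness ratio (ICER) against the Thai willingness-to-pay ceiling
of THB 160,000 per QALY.

This vignette is the package's methods account: the model and its
assumptions, the parameters that matter, the design choices made where the
original description is open to interpretation, and what the synthetic-data
generators do and do not emulate.

# Disease and screening model

## States

Health states are `no_cancer`, `precancer` (oral potentially malignant
disorder), invasive cancer stages I–IV, and death.  Every disease state is
crossed with a treatment status — `undetected`, `on_treatment`, or
`detected_untreated` (diagnosis confirmed but treatment refused) — giving a
17-state space.  `no_cancer` is always undetected; death is absorbing.

## Cycle structure

Within a one-year cycle, events compose in a fixed order:

1. **Death.**  No-cancer and precancer states die at the age-specific
   background probability from the bundled life table; invasive stages die
   at their stage-specific all-cause probabilities (treated patients at the
   tabulated values 0.20/0.34/0.42/0.52, untreated at hazard ratio 2),
   which are *not* added to background mortality (avoids double counting).
2. **Detection.**  Survivors in undetected states are confirmed this cycle
   with the cascade probability for their state and routed to
   `on_treatment` with the stage's treatment compliance, otherwise to
   `detected_untreated`.
3. **Progression / regression.**  Probabilities follow the post-detection
   status: untreated stage progression at the tabulated values, on
   treatment at `hr_adjust(p, 0.5)`; untreated precancer regresses to
   no-cancer at 0.30/yr, treated precancer is cured at 0.58/yr, and treated
   precancer additionally progresses to stage I at 0.01/yr through loss to
   follow-up (supplementing the hazard-adjusted progression; switchable).

The hazard-ratio transform is rate-based, `p' = 1 − (1 − p)^HR`, which
keeps probabilities in [0, 1) and composes multiplicatively; a
multiplicative variant is available (`options$hr_transform`).  There is no
half-cycle correction by default (the original model was
spreadsheet-based); `options$half_cycle_correction` enables trapezoidal
accrual.

## The screening cascade

`evaluate_cascade()` walks a person of known true state through the ordered
steps.  Attendance at each step follows the state-class compliance and
incurs the step's full cost (fee, transport, lost productivity).  Diseased
persons continue only on a true positive (precancer sensitivities from the
accuracy block; invasive cancer is assumed never missed once attended), and
diagnosis requires biopsy attendance at the end of the chain.  Disease-free
persons propagate on false positives and are released at the confirmation
step for the no-cancer state (VETDT in the screening programme, the oral
surgeon in usual care); specificity losses therefore generate cost but
never a misassigned diagnosis, because the cohort model tracks true state.
Anyone exiting early — by non-attendance or a negative result — keeps their
state and re-enters the cascade at step 1 next year.  Test results and
attendance are independent across steps given the true state; no
correlation structure is reported.

An optional `fp_workup: "full"` mode additionally sends false positives at
the confirmation step through the remaining examinations and a rule-out
biopsy before release, matching the alternative reading of the programme
description in which the oral surgeon confirms "true and false positives"
by biopsy.  The default (`"release"`) stops them at the dentist.

Usual care is the same evaluator with self-referral as first-step
compliance (0.04 disease-free and precancer, 0.43 stages I–II, 0.82 stages
III–IV), general-dentist accuracy, oral-surgeon examination and biopsy
compliance 0.51.

## Costs and QALYs

Screening costs accrue per cycle as expected cascade cost times the
occupancy of screenable states (disease-free and undetected).  Cancer
treatment costs are episode costs charged once on entry to `on_treatment`
(including progression to a higher stage while on treatment);
`options$cancer_cost_timing = "annual"` switches to per-treated-year
charging.  Precancer treatment is follow-up care charged per treated year.
Utilities are 1.0 disease-free, 0.83 precancer, 0.61 stages I–II, 0.34
stages III–IV, 0 dead; treated and untreated persons in a stage share the
stage utility.  `options$undetected_precancer_utility = "healthy"` lets an
undiagnosed asymptomatic lesion carry the healthy utility instead (the
utilities were elicited from diagnosed patients).  Costs and QALYs are
discounted at 3% per annum, cycle 0 undiscounted.

# Parameters

Every quantity lives in one YAML document
(`inst/extdata/default_config.yaml`) as `(mean, se, family, group)`.
Probabilities and utilities with uncertainty are Beta, costs are Gamma,
both moment-matched:

$$\alpha = m\left(\frac{m(1-m)}{s^2} - 1\right),\qquad
  \beta = (1-m)\left(\frac{m(1-m)}{s^2} - 1\right)$$

for Beta (feasible only when $s^2 < m(1-m)$, asserted at load time), and
shape $m^2/s^2$, scale $s^2/m$ for Gamma.  `confidence_bounds()` returns
distribution quantiles, the ranges used by the one-way tornado.

Three parameter groups deserve comment:

* **Precancer onset** (`p_no_cancer_to_precancer`, default 0.0058/yr) is
  not printed in the source evaluation; it is anchored to the national oral
  cancer incidence and explicitly calibrated so the cohort reproduces the
  published base-case cost and QALY increments.  It is a plain config value.
* **Programme management cost** is printed as "0.25" with unclear units.  A
  quarter-baht per person per year cannot represent trainings, printed
  questionnaires and health-worker incentives, so the default reads it as a
  25% overhead on delivered screening services
  (`management_as_fraction: true`); a flat THB amount is the alternative.
* **Compliance, cure, loss to follow-up and the two hazard ratios** are
  printed without standard errors, but the original analysis varies them
  over 95% confidence intervals, so the default config attaches binomial
  standard errors at an effective pilot sample of n = 20 (probabilities)
  and a 30% coefficient of variation (hazard ratios).  With these, the
  upper-CI ICER for dentist-examination compliance comes out within 2% of
  the published one-way result.  Assumed 100% attendance and accuracy for
  symptomatic invasive cancer stays fixed.  Unit fees from reimbursement
  schedules stay fixed.

The life table is a bundled *synthetic* fixture
(`thai_life_table_synthetic.csv`): Gompertz–Makeham annual death
probabilities fitted once to the scale of Thai adult mortality (remaining
life expectancy at 40 about 36.6 years; 3%-discounted life expectancy about
21.7 years).  It is replaceable through the `life_table` config key, either
as a CSV path or an inline age→qx map.

# Analysis layer

* `run_base_case()` — deterministic comparison at parameter means.
* `run_psa(n, seed)` — Monte-Carlo parameter uncertainty: each draw samples
  every distributed parameter independently from its moment-matched
  distribution, re-runs both arms, and feeds the cost-effectiveness
  acceptability curve CEAC(λ) = P(λ·ΔQALY − Δcost > 0).  Draws producing an
  infeasible transition structure are rejected and redrawn (counted;
  essentially never triggered at the default values).  Identical seeds give
  bit-identical draws.
* `one_way()` / `tornado()` — deterministic re-runs at the 2.5th/97.5th
  percentiles of one parameter, sorted by induced ICER range.
* `two_way()` — an ICER surface over a ±20% grid of two parameters, or the
  *paired* mode that sets one step's sensitivity and specificity to a
  common value and interpolates where the ICER crosses the
  willingness-to-pay contour (the construction behind "the programme
  becomes cost-effective once MSE accuracy reaches about 60%").
* `run_scenarios()` — programme variants: A the full cascade, B without
  MSE, C without MSE and VETDN, D without VETDN, all against the common
  usual-care comparator.

# Synthetic data

The `synthetic_data` generators make every input reproducible without any
download:

* `generate_tto_responses()` emulates time-trade-off interviews: each
  respondent's indifference point is the true utility plus truncated-normal
  noise on the utility scale, rounded to whole years out of ten (the
  questionnaire offered 0–9 years in full health against 10 years in the
  state, with indifference at 10).  The default noise SD (0.055) makes a
  nine-patient interview yield a standard error near 0.02, matching the
  precancer utility row.  `tto_utility()` is the matching estimator
  (mean of years/10, SE = SD/√n).
* `generate_cost_records()` draws gamma patient-level cost amounts whose
  sample mean has, by construction, the stated standard error at the stated
  interview size (patient-level variance n·SE²).
* `perturb_parameter_table()` jitters all distributed means within a
  relative band and clips back into each family's feasible region, for
  property-based fuzzing of the whole pipeline.

These generators emulate scale and precision, not realism: no interviewer
or hospital effects, no non-response, no correlation between cost
components, no EQ-5D mapping.  Passing the recovery tests shows the
estimators and the moment machinery are consistent, not that the field data
behaved this way.

# Numerical choices and degenerate inputs

Cohort conservation is asserted to 1e-9 each cycle and transition rows to
1e-10; the cascade evaluator is property-tested to 1e-12 against an
exhaustive enumeration of every attendance/result branch.  Degenerate
configurations behave predictably: zero first-step compliance leaves only
management cost; zero incidence reduces lifetime QALYs exactly to the
discounted life expectancy of the life table; a "screening" programme
identical to usual care produces zero increments and an undefined ICER
(flagged, never divided).  Probabilities at 1 saturate under the hazard
transform.  The simulation spans 60 cycles (ages 40–99 accrue; the cohort
is censored at 100); the default PSA uses 1,000 draws, the paired
two-way sweeps use a 0.40–0.95 accuracy grid in steps of 0.05.

# Fidelity and known limitations

With the default configuration the package reproduces the published
evaluation's headline results: the base-case ICER within 1%, cost and QALY
increments within 16%, the upper-CI one-way results for MSE sensitivity and
dentist-examination compliance within 12% and 2%, the common-accuracy
two-way points within 15–20%, and the acceptability at the Thai threshold
within 3 percentage points.  Absolute per-arm cost levels are lower than
published (the increments, which drive every decision quantity, are the
calibration targets); this is expected when a spreadsheet model is rebuilt
from its printed parameter table alone.

The published scenario comparison ranks "MSE + dentists + surgeons"
(scenario D) as more cost-effective than "dentists + surgeons only"
(scenario C).  Under the annual-regression structure this package defaults
to, C always dominates D: with precancerous lesions resolving or
progressing within about three years, detection probability translates
almost linearly into QALY gain, and C detects five times more than D at
less than four times the incremental cost.  The published pattern requires
strong saturation of detection benefit — lesions persisting for decades —
which the package offers as the lesion-level regression reading
(`regression_timing: "at_onset"`: 30% of incident lesions resolve at onset,
the remainder persist).  That reading reproduces the published scenario
ordering and levels but overdrives the model's response to accuracy
improvements, moving the two-way thresholds and the acceptability curve
away from their published values.  No single configuration we found
satisfies both; the published scenario table is also internally
inconsistent (its printed cost and QALY columns do not reproduce its own
printed ICERs), so the default keeps the annual-regression structure and
the scenario comparison is reported as-is.

Further limitations: a closed cohort with time-constant parameters (no
secular trends, no age-dependence of disease parameters); perfect biopsy;
no waiting times within a cycle; no correlation between sampled parameters;
indirect costs of premature death excluded.
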