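# oralscreen

Markov cohort cost-utility model of Thailand's population-based oral
precancer screening programme.

Oral cancer in Thailand is usually diagnosed late, when treatment is
expensive and survival poor, while precancerous lesions (potentially
malignant disorders) are curable.  The national pilot programme screens
everyone over 40 each year through a four-step cascade — mouth
self-examination (MSE), visual examination by trained dental nurses
(VETDN), by trained dentists (VETDT) and by oral surgeons (VEOS), with
biopsy confirmation — and the policy question is whether that cascade is
worth its cost compared with leaving detection to self-referral.
`oralscreen` is for health-economic modellers who want that evaluation as
inspectable, testable, re-configurable code rather than a spreadsheet.

## Model

A closed cohort enters disease-free at age 40 and is followed in one-year
cycles to age 100 through states
`no cancer → precancer → stage I → … → stage IV → death`, each disease
state crossed with a treatment status (undetected / on treatment /
detected-but-refused).  Per cycle: background or stage-specific death;
confirmed detection through the screening cascade (each step attended with
a state-specific compliance, passed with its sensitivity, false positives
costed through specificity); then progression, regression (0.30/yr
untreated) or cure (0.58/yr treated), with treated progression and
untreated mortality scaled through p′ = 1 − (1 − p)^HR (HR 0.5 and 2).
Costs (2016 THB, societal: fees, transport, lost productivity, treatment
episodes) and utility-weighted life years (TTO utilities 0.83 / 0.61 /
0.34) are discounted at 3%/yr and compared as

ICER = (C_screen − C_usual) / (Q_screen − Q_usual),

judged against the Thai threshold λ = 160,000 THB/QALY.  Parameter
uncertainty propagates through moment-matched Beta/Gamma distributions
(probabilistic sensitivity analysis → cost-effectiveness acceptability
curve); deterministic uncertainty through one-way (tornado) and two-way
analyses; programme design through scenarios that drop low-accuracy steps.
All inputs live in one YAML document bundled with the package.

## Worked example

```r
library(oralscreen)

model <- load_model()                 # bundled Thai programme configuration
bc <- run_base_case(model)

psa <- run_psa(model, n = 1000, seed = 42)
ceac_at(psa, 160000)

tw <- two_way(model, "mse", mode = "paired", values = seq(0.4, 0.95, 0.05))
tw$crossing
```

prints (formatted):

```
Screening:        1879 THB   21.4676 QALYs
No screening:      726 THB   21.4639 QALYs
Increment:        1153 THB    0.0037 QALYs
ICER: 308675 THB/QALY (threshold 160000)
P(cost-effective at 160k): 0.263
MSE accuracy where ICER crosses 160k: 0.55
```

Read: screening adds about 1,150 THB and 0.004 QALYs per person over a
lifetime, an ICER of roughly 309,000 THB per QALY — nearly double the Thai
willingness-to-pay ceiling, so the four-step programme is not
cost-effective as designed, with about a one-in-four chance of being
cost-effective once parameter uncertainty is considered.  The paired
two-way analysis says the verdict flips if mouth self-examination reached
~55–60% sensitivity and specificity.  `run_scenarios(model)` compares the
reduced cascades (dropping MSE and/or the dental-nurse step), which all
fall below the threshold; `tornado(model)` ranks parameter influence.

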