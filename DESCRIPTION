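Package: oralscreen
Title: Cost-Utility Modelling of Multi-Step Oral Cancer Screening Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov cohort decision model for evaluating the cost-utility of
    population-based oral precancer screening programmes organised as ordered
    cascades of imperfect, imperfectly attended visual examinations.  Provides
    moment-matched Beta and Gamma parameter distributions, screening-cascade
    evaluation with false-positive costing, discounted cost and QALY
    accounting over a lifetime horizon, ICER and net-monetary-benefit
    computation, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, one-way (tornado) and two-way sensitivity analyses,
    scenario comparison of reduced cascades, and synthetic-data generators for
    time-trade-off utility interviews and patient cost records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
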