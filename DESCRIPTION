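Package: apixcea
Title: Lifetime Markov Cohort Cost-Effectiveness Model of Apixaban
    versus LMWH/VKA for Venous Thromboembolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime Markov cohort state-transition model comparing
    18-month apixaban against 6-month and 18-month low-molecular-weight
    heparin/vitamin K antagonist (LMWH/VKA) treatment of venous
    thromboembolism, from a UK NHS perspective.  Implements the full model
    input set with 95 percent confidence intervals, constant-hazard
    rate/probability conversions with competing-risk allocation, life-table
    background mortality with condition-specific excess hazard ratios,
    per-cycle cost and quality-adjusted life-year accrual with 3.5 percent
    annual discounting, and the standard decision-analytic toolkit:
    deterministic base case with incremental cost-effectiveness ratios,
    one-way (tornado) sensitivity analysis, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and
    treatment-duration scenario analyses.  A deterministic synthetic life
    table and closed-form toy models allow the whole pipeline to run and be
    tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
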