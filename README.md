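# apixcea

A lifetime Markov cohort cost-effectiveness model comparing **18-month
apixaban** against **6-month** and **18-month LMWH/VKA** (low-molecular-
weight heparin bridging plus vitamin K antagonist) for the treatment of
venous thromboembolism (VTE) and prevention of recurrences, from a UK NHS
perspective.

It is written for health economists and methodologists who want a fully
scripted, testable implementation of this class of anticoagulation
decision model: every input (risks with 95% CIs, relative treatment
effects, event-type splits, costs, utilities, population, policy rules)
is data, every analysis is a function, and the whole pipeline runs with
no external downloads via a packaged parameter fixture and a deterministic
synthetic life table.

## The model

A cohort enters at an index VTE (mean age 56.9, 58.7% male, 65.8% DVT) and
steps through 3-month cycles until extinction. Each cycle the alive cohort
faces competing risks — recurrent VTE (non-fatal DVT/PE or VTE death),
major bleeding (fatal / intracranial / other), clinically relevant
non-major bleeding, adverse-event discontinuation, CTEPH onset (PE
history), other-cause death — combined under constant hazards: for
marginal probabilities *p<sub>j</sub>* with hazards
*r<sub>j</sub> = −log(1−p<sub>j</sub>)*, total event probability
*P = 1 − exp(−Σr<sub>j</sub>)* is allocated in proportion to
*r<sub>j</sub>*. Relative treatment effects act on the hazard scale,
*p′ = 1 − (1−p)<sup>RR</sup>*; bleeding hazards rise 1.97× per decade of
age after month 18. Background mortality comes from an annual life table
with condition-specific excess hazard ratios. Severe post-thrombotic
syndrome is tracked as a background prevalence with a lifelong utility
decrement. Per cycle *k*, costs and QALYs accrue on start-of-cycle
occupancy discounted by 1.035<sup>−0.25k</sup>, and strategies are
compared by the ICER ΔCost/ΔQALY against a £20,000/QALY threshold, with
net-monetary-benefit (NMB = λ·QALY − Cost) ranking in the probabilistic
analysis.

Analyses: deterministic base case, one-way (tornado) sensitivity over
every parameter with interval evidence, probabilistic sensitivity
analysis (2000 draws; beta/gamma/lognormal distributions moment-matched
to each mean and 95% CI) with cost-effectiveness acceptability curves,
and treatment-duration scenarios up to lifelong treatment.

## Worked example

```r
library(apixcea)
p  <- default_parameters()   # packaged input set, 95% CIs attached
lt <- generate_life_table()        # synthetic UK-like annual life table
bc <- run_base_case(p, lt)
bc
#> <vte_base_case>
#>   apixaban-18m   £   5903  10.965 QALY  13.488 LY
#>   lmwh_vka-6m    £   5213  10.853 QALY  13.373 LY
#>   lmwh_vka-18m   £   5369  10.902 QALY  13.449 LY
#> <vte_incremental apixaban-18m vs lmwh_vka-6m>
#>   dCost £690  dQALY 0.1119  dLY 0.1158  ICER £6167/QALY
#> <vte_incremental apixaban-18m vs lmwh_vka-18m>
#>   dCost £534  dQALY 0.0630  dLY 0.0391  ICER £8476/QALY
```

Read this as: per patient (discounted, lifetime), 18-month apixaban costs
£690 more than a 6-month LMWH/VKA course but yields 0.112 extra QALYs —
about £6,167 per QALY gained, well under the usual £20,000 willingness-to-
pay; against 18-month LMWH/VKA the ICER is £8,476. `bc$table` holds the
full result table (lifetime events per 1000 patients, cost categories,
LYs, QALYs); `bc$vs_6m$d_events` gives event differences, e.g. ~56 fewer
recurrent VTEs and ~13 fewer major bleeds per 1000 versus the 6-month
course.

Further entry points:

```r
run_owsa(p, lt, comparison = "vka6")          # tornado table
run_psa(p, lt, n_draws = 2000, seed = 1)      # CEAC + draw cloud
run_scenario_durations(p, lt, Inf, 6)         # lifelong apixaban vs 6m VKA
auxiliary_sensitivity(p, lt)                  # sensitivity to assumption inputs
render_report("out/", bc, p = p)              # markdown + CSV bundle
```

A command-line front end is provided at `inst/cli/apixcea.R`
(`fixture | base | owsa | psa | scenario` subcommands). Parameter files
are YAML (`write_parameters()` / `load_parameters()`, strict keys,
partial overrides allowed); life tables are `age,qx_male,qx_female` CSVs.

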