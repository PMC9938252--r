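Package: brcacea
Title: Cost-Effectiveness Analysis of Germline BRCA Testing Strategies in
    Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of germline BRCA1/2 testing policies
    (no testing, family-history-selected testing, universal testing) for
    triple-negative and all HER2-negative breast cancer cohorts in China and
    the USA. A decision tree stratifies the cohort by family history, carrier
    status, detection and risk group; each stratum is evaluated with a
    three-state (disease-free, recurrence, death) Markov cohort model with
    half-cycle correction and discounting. Strategies are compared with
    incremental cost-effectiveness ratios, net monetary benefit and a
    cost-effectiveness frontier, and uncertainty is quantified with one-way
    deterministic sensitivity analysis (tornado) and probabilistic
    sensitivity analysis (Monte Carlo with beta, gamma and log-normal
    parameter distributions, acceptability curves and cost-effectiveness
    planes). A synthetic parameter-table generator and an individual-level
    microsimulation oracle support fully reproducible, download-free runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
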