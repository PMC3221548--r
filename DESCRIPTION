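Package: riskstrat
Title: Simulation and Evaluation of Genetic Risk Stratification
Version: 0.1.0
Authors@R:
    person("riskstrat", "maintainers", email = "riskstrat@example.org",
           role = c("aut", "cre"))
Description: Simulates cohorts in which risk-genotype frequencies, per-variant
    effect sizes and the population disease risk match prespecified values,
    builds genetic risk scores (risk-genotype counts, Bayes posterior risks,
    and logistic-regression predicted risks), and characterises screening
    performance across all possible high-risk thresholds: sensitivity,
    specificity, positive and negative predictive value, the frequency of the
    high-risk group, and rank-based AUC with confidence intervals. Includes a
    scenario runner that averages the full threshold/metric surface over
    replicate cohorts, a panel-size sweep, and a six-locus age-related macular
    degeneration example driven by a packaged parameter table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
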