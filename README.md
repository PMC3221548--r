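# riskstrat

Simulation and evaluation of genetic risk stratification.

## What this package is for

Genetic risk models (polygenic scores, multi-locus panels) are often
proposed for identifying "high-risk groups" to target prevention. Whether
that works depends on three interacting quantities: the model's
discriminative accuracy (AUC), the frequency of disease in the population
(*p*), and the frequency of the high-risk group that the chosen threshold
defines (*q*). `riskstrat` is for epidemiologists and methodologists who
want to study those interactions exactly, on simulated cohorts whose genetic
architecture is fully known.

The package

* simulates cohorts of *n* individuals carrying *m* independent binary risk
  genotypes so that the genotype frequencies *f*, the per-variant effect
  sizes and the population disease risk *p* match prespecified values —
  either risk-first under a capped multiplicative **risk** model
  (`effect_model = "multiplicative_risk"`, the default), or status-first
  under a multiplicative **odds** model whose case/control genotype
  frequencies (a, b) solve `p·a + (1−p)·b = f` and
  `[a/(1−a)]/[b/(1−b)] = OR`;
* builds risk scores: the count of risk genotypes, the Bayes posterior risk
  `odds = p/(1−p) · Π LR_j`, and logistic-regression predicted risks for
  categorical genotypes;
* computes the full screening surface at **every** threshold *t* (high risk
  = score ≥ t): sensitivity, specificity, PPV, NPV, the group frequency
  *q*, and the rank-based (Mann–Whitney) AUC with DeLong or Hanley–McNeil
  confidence intervals;
* averages everything over replicate cohorts and reproduces a complete
  published-style results grid (three headline 50-variant scenarios, a
  5–600-variant panel-size sweep, and a six-locus age-related macular
  degeneration scenario).

The core identity the package makes visible is the **ratio law**: on any
cohort, `sens / PPV = q̂ / p̂` exactly, so sensitivity and PPV can only be
jointly high when the high-risk group is about as common as the disease.

## Worked example

```r
library(riskstrat)

cfg <- scenario_config(10000, 0.3, n_variants = 50, frequency = 0.3,
                       odds_ratio = 1.5, n_replicates = 100, seed = 1)
res <- run_scenario(cfg)
res
#> experiment: 100 replicate(s), mean AUC = 0.8784 (MC SE 0.0004)

subset(res$metrics_by_threshold, threshold %in% c(13, 15, 17),
       select = c(threshold, highrisk_frequency, sensitivity, specificity,
                  ppv, npv))
#>    threshold highrisk_frequency sensitivity specificity   ppv   npv
#> 14        13              0.777       0.974       0.307 0.376 0.965
#> 16        15              0.553       0.901       0.595 0.488 0.934
#> 18        17              0.316       0.730       0.861 0.692 0.882
```

At threshold 15 the high-risk group holds 55% of the cohort: it captures 90%
of future cases (sensitivity) but fewer than half of its members will
develop disease (PPV 0.49). Tightening the group to the top ~10% of scores
flips the trade-off — the ratio law caps sensitivity near q/p:

```r
summarize_at_group_frequency(res, 0.10)[c("achieved_q", "threshold",
                                          "sensitivity", "ppv")]
#>   achieved_q threshold sensitivity ppv
#> 1      0.085        20        0.28   1
```

The six-locus AMD scenario (logistic predicted risks from a packaged
parameter table; the table is a synthetic literature-based stand-in, see the
methods vignette):

```r
run_amd_experiment(seed = 7)
#> six-locus categorical-genotype risk-prediction experiment
#> AUC = 0.7591 (95% CI 0.7426-0.7756, delong; 918 cases, 9082 controls)
#> predicted risks span 0.0026 .. 0.6960 (prevalence 0.09)
```

## Command line

```sh
inst/cli/riskstrat run --config scenario.json --reps 100 --out results/
inst/cli/riskstrat reproduce fig4 --out results/
inst/cli/riskstrat amd --n 10000 --prevalence 0.09 --out results/
```

`scenario.json` holds `n_individuals`, `disease_risk`, `n_replicates`,
`seed` and either a `variants` array or the shorthand
`{n_variants, frequency, odds_ratio}`. Outputs are CSV tables
(`metrics_by_threshold.csv`, `auc_summary.csv`, sweep tables) plus a JSON
run manifest that re-runs bit-identically.

## Package layout

* `R/cohort_sim.R` — scenario configs, case/control frequency solver, cohort
  simulator (both effect models), replicate seed streams
* `R/amd.R` — categorical-genotype simulation and the parameter-table format
* `R/risk_models.R` — count score, Bayes risk, logistic predicted risks
* `R/stratification.R` — threshold tables, AUC/CIs, threshold selection
* `R/experiments.R`, `R/reproduce.R` — replicate runner, panel-size sweep,
  AMD experiment, figure-table reproduction
* `R/io.R`, `R/cli.R` — JSON configs, CSV/manifest output, CLI
* `vignettes/risk-stratification-methods.Rmd` — models, assumptions,
  numerical choices, limitations
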