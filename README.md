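# radonvuln

Threshold-indexed indoor radon vulnerability classification and ecologic
lung cancer mortality trends.

## What this package is for

Radon guideline values — 50 to 600 Bq/m³ depending on the jurisdiction —
are remediation triggers, not safety levels, and any risk map built from a
guideline inherits its choice of threshold. This package implements, as a
tested and reusable pipeline, an ecologic analysis of how that choice plays
out across a province of small spatial mapping units (census areas
intersected with bedrock geology):

- **Vulnerability labels.** A measured unit is *high* vulnerability at
  threshold $T$ when its observed 95th percentile indoor radon
  concentration satisfies $P_{95} \ge T$ (order-statistic interpolation at
  $h = (n-1)p + 1$). Labels nest down the threshold ladder
  $\{50, 100, 150, 200, 300, 400, 500, 600\}$ Bq/m³.
- **Class-balanced bootstrap forest.** Per threshold, an ensemble of
  maximally grown Gini classification trees, each trained on a bootstrap
  sample drawing the minority-class size from *each* class, with pooled
  out-of-bag (OOB) evaluation: per-class accuracy and precision, Cohen's
  kappa $\kappa = (p_o - p_e)/(1-p_e)$, and the kappa *gain* between
  adjacent thresholds. Geary's $c$ with a permutation test diagnoses
  spatial autocorrelation of the response.
- **Mapping and population at risk.** Unmeasured units are classified per
  threshold (units with categorical covariate levels unseen in training are
  `INELIGIBLE`); populations reach units by areal apportionment
  (population × unit area / parent area) and aggregate conservatively to
  regional summaries and fold changes.
- **Mortality trends.** Adult natural deaths (ICD-10 codes not starting
  T–Y, age ≥ 20; lung cancer = C34*) are stratified by vulnerability class,
  health-area smoking split (above/below median prevalence) and sex; annual
  crude lung cancer mortality ratios (lung / all natural deaths) are
  smoothed with a tricube local regression, and an exact expected-count
  sensitivity analysis probes ecologic misclassification.
- **Synthetic studies.** Because real inputs of this kind are confidential
  vital-statistics archives, `synthesize_study()` generates a full province
  with known ground truth — log-normal indoor radon by geology class,
  covariates with recoverable signal, apportionable populations, and death
  records whose lung cancer fraction follows a logistic model with
  configurable odds ratios — so every stage is testable end to end.

It is aimed at environmental-health analysts who want to study guideline
sensitivity, and at methodologists who need a transparent, reproducible
reference implementation of balanced-forest ecologic risk classification.

## Worked example

```r
library(radonvuln)

study    <- synthesize_study(generator_config(seed = 1))
study
#> Synthetic radon study
#>   units:        2022 (in 800 parent areas, 8 regions)
#>   measured:     528 units, 2102 measurements
#>   health areas: 83
#>   deaths:       209872 over 16 years

training <- build_training_set(study$units, study$measurements)
training$class_distribution
#>   threshold n_high n_low
#> 1        50    441    87
#> 4       200    253   275
#> 8       600     83   445      (abridged)

models <- train_ladder(study$units, training$labels,
                       config = forest_config(n_runs = 5, n_trees_per_run = 100,
                                              seed = 2))
round(ladder_metrics(models), 3)
#>   threshold accuracy_low precision_low accuracy_high precision_high kappa kappa_gain
#> 1       600        0.701         0.937         0.747          0.318 0.289      0.000
#> 2       500        0.721         0.934         0.819          0.452 0.418      0.129
#> 5       200        0.673         0.841         0.862          0.708 0.530      0.044
#> 7       100        0.682         0.766         0.899          0.853 0.597      0.015
#> 8        50        0.713         0.544         0.882          0.940 0.529     -0.069   (abridged)
```

The table reads like the study design intends: as the threshold drops the
classes balance (441/87 at 50 vs 83/445 at 600 Bq/m³), and the high class
becomes much easier to find — its precision climbs from 0.32 to 0.94 and
kappa from 0.29 to ~0.6, with the largest gains at the big threshold
reductions. Mapping the province and apportioning populations:

```r
maps      <- build_threshold_maps(models, study$units)
summaries <- summarize_regions(maps, study$units)
population_fold_change(summaries, 200, 50)
#> [1] 1.716792
```

i.e. lowering the guideline from 200 to 50 Bq/m³ puts ~1.7× as many
(synthetic) residents into high-vulnerability areas. `run_pipeline()`
wires all stages together — simulate → label → train → metrics → map →
trends — writing CSV artifacts plus a hash manifest, and is byte-identical
under a fixed seed.

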