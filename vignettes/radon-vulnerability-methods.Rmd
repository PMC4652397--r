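---
title: "Methods: threshold-indexed radon vulnerability classification and mortality trends"
author: "radonvuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-indexed radon vulnerability classification and mortality trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonvuln)
```

## The problem

Indoor radon is a non-threshold lung carcinogen: guideline values (50 to
600 Bq/m³ across jurisdictions) do not mark safe concentrations, they mark
concentrations above which remediation is recommended. Because risk maps are
built relative to a chosen guideline, the guideline itself changes which
areas — and how many people — are labelled at risk, and how well the label
can be predicted at all. This package implements an ecologic pipeline for
studying exactly that sensitivity:

1. **Vulnerability labelling.** Each small spatial mapping unit (a census
   area intersected with a bedrock geology class) that has indoor radon
   measurements is labelled *high* or *low* vulnerability at each threshold
   $T$ in a ladder, according to whether its observed 95th percentile
   concentration $P_{95}$ satisfies $P_{95} \ge T$.
2. **Classification.** A class-balanced bootstrap forest is trained per
   threshold on geology, soil/climate-style and housing-style covariates,
   and evaluated out-of-bag (OOB).
3. **Mapping.** Unmeasured units are classified by each model; units whose
   categorical covariates take levels unseen in training are *ineligible*.
   Populations at risk are estimated by areal apportionment.
4. **Trends.** Death records are filtered to adult natural deaths, assigned
   to the strata of their unit and health area, and the annual crude lung
   cancer mortality ratio (lung deaths / all natural deaths) is compared
   between strata with a local (LOESS-type) smoother.

Real inputs of this kind are typically confidential vital-statistics and
survey archives, so the package ships a synthetic-study generator with known
ground truth; every stage is exercised and tested end to end on it.

## Vulnerability labels

`percentile_95()` uses linear interpolation of order statistics at plotting
position $h = (n-1)p + 1$ (the `quantile(type = 7)` convention). The
convention is pinned for bit-reproducibility; the literature of this kind of
analysis rarely states one. A unit with a single measurement is labelled
from that value — the design requires only *at least one* measurement.

A value exactly at the threshold is classified **high**. Guidance framed
around keeping exposure as low as reasonably achievable makes the
at-guideline case actionable, so the inclusive rule is the conservative one
for a screening product.

Labels are *nested* by construction: high at $T$ implies high at every
lower threshold, so the high-class count is non-increasing in $T$. That
nesting — and its mirror in class imbalance — is the central structural
fact of the ladder: at 600 Bq/m³ the high class is a small minority; at
50 Bq/m³ the classes are nearly balanced.

## The class-balanced bootstrap forest

Each tree draws a bootstrap sample of $n_{\min}$ observations *with
replacement from each class*, where $n_{\min}$ is the minority class size
(`balanced_bootstrap()`); every tree therefore trains on an exactly
balanced sample and the units it did not draw are its OOB set. Trees are
CART-style, grown maximally (`min_leaf_size = 1`):

* each split examines a random subset of $\lceil\sqrt{d}\rceil$ covariates;
* continuous splits consider midpoints between consecutive observed values;
* categorical splits order the node's levels by their high-class proportion
  and scan prefix partitions — for binary outcomes and Gini impurity this
  ordering contains the optimal subset split, avoiding the $2^{K-1}$
  subset search;
* the split maximizing the Gini impurity decrease wins; ties and exhausted
  nodes become leaves predicting the majority class (tie → high).

The ensemble is organised as `n_runs` runs of `n_trees_per_run` trees whose
OOB vote tallies are pooled; pooling runs is equivalent to one larger
forest, and the run structure exists for seed bookkeeping (run $r$ draws
from substream $r$ of the forest seed). The design-scale configuration is
20 runs × 10,000 trees; the desk default is 20 × 200, and the package's own
experiments use 5 × 100 per threshold — OOB estimates on a few hundred
training units are already stable at a few hundred trees, and an
8-threshold ladder then fits in about a second.

A unit's OOB prediction is the majority of its pooled OOB votes (tie →
high); units never OOB (vanishingly rare beyond ~50 trees; coverage below
99 % warns) are excluded from metrics. Prediction for new units is the
majority vote over all trees, with one eligibility rule first: any
categorical level unseen in training makes the unit `INELIGIBLE` rather
than silently routed through the trees.

Tree growth is implemented in C++ (Rcpp) as the field's forest packages do;
all randomness flows through R's RNG, so `set.seed()` governs the whole
ensemble. `randomForest` with stratified equal-size sampling serves as an
independent cross-check in the test suite, never as the implementation.

## Performance metrics

From the OOB confusion matrix (rows observed, columns predicted):
class *accuracy* is the proportion of an observed class correctly
classified (row-wise); class *precision* the proportion of a predicted
class correctly classified (column-wise); zero denominators yield missing
values, not zeros. Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ corrects agreement for chance and is the
headline summary under imbalance ($p_e = 1$ returns 0 by convention). The
*kappa gain* at threshold $T_i$ is $\kappa(T_i) - \kappa(T_{i+1})$ against
the next-higher threshold, the highest threshold gaining 0 — the quantity
that expresses how much classification improves as a guideline is lowered.

`geary_c()` implements Geary's $c$,
$$c = \frac{(N-1)\sum_{ij} w_{ij}(x_i-x_j)^2}{2W\sum_i (x_i-\bar x)^2},$$
with expectation 1 under no spatial autocorrelation, plus a two-sided
permutation test (default 999 relabelings, add-one-corrected tail
probability, doubled and capped at 1). The weight matrix is symmetrized
8-nearest-neighbour adjacency on unit centroids — a spatial-weights choice
the package documents rather than inherits, since none is canonical for
irregular mapping units; both $k$ and the matrix are user-replaceable.

## Mapping and population at risk

Populations reach mapping units by areal apportionment: a unit receives its
parent census area's population times the fraction of the parent's area it
covers (500 residents in 2 km² split into two 1 km² units → 250 each).
Values stay fractional through every aggregation so population is conserved
exactly (unit → parent → region → province, tolerance 1e-6 in tests);
rounding, if wanted, is a reporting step (half-to-even). Regional summaries
report the area-weighted fraction of eligible units classified high and the
population in high, low and ineligible units — ineligible population is
reported separately, never folded into low. `population_fold_change()`
compares the high-class population between two thresholds.

Per-threshold maps come from independently trained models, so predicted
high sets need not nest exactly even though the labels do; the expected
monotone trend is checked softly (a warning, not an error).

## Mortality trends

`filter_deaths()` keeps records aged ≥ 20 whose cause code does not start
with T–Y (external causes; note V is inside that range), flagging codes
starting with "C34" as lung cancer; malformed codes are dropped with a
counted warning. Health areas are split at the median smoking prevalence
(midpoint convention for even counts; exactly-at-median → lower). Deaths in
ineligible units are excluded from trend denominators — assigning them low
would dilute the low stratum — and are counted in an exclusion log.

The annual crude lung cancer mortality ratio is lung deaths over all
natural deaths per stratum-year. Curves are smoothed with a locally
weighted regression: at each year, a weighted polynomial (degree 2, span
0.75 by default; both tunable) over the $q=\lceil \text{span}\cdot n\rceil$
nearest years with tricube weights
$w = (1-(d/d_{\max})^3)^3$. Points exactly at $d_{\max}$ get weight zero,
so the neighbourhood grows until at least degree + 1 points have positive
weight; with all-tied distances weights are uniform. This smoother is
implemented directly because its exact neighbourhood and weight conventions
are part of the package's contract (tests verify equality with an
independent normal-equations oracle at 1e-9; `stats::loess` uses related
but not identical conventions).

The stratum summary table reports, per stratum, the percentage of all
natural deaths, the percentage of all lung deaths, and their ratio. The
ratio is computed by default from percentages rounded to one decimal — the
convention of printed summary tables, so 26.2/22.9 → 1.14 — with
`from_rounded = FALSE` switching to unrounded counts.

`misclassification_sensitivity()` quantifies ecologic exposure
misclassification with exact expected-count arithmetic: fractions
`f_lung`/`f_other` of the high group's lung and other natural deaths are
moved to the low group and both within-group ratios recomputed; totals are
conserved by construction and no resampling is involved.

## The synthetic-study generator

The generator emulates the *structure* of a provincial study — it is the
package's study condition, not a tuning surface:

* ~800 parent census areas on a grid, split by a Dirichlet draw into ~2,000
  mapping units (areas conserve exactly), six geology classes whose
  prevalence shifts towards radon-prone classes across 8 regions;
* indoor radon is log-normal per unit — geometric mean set by geology
  (defaults 15–170 Bq/m³) with 15 % unit-level log-jitter, geometric
  standard deviation 2.2–3.2 — the conventional distributional model for
  indoor radon. These scales put the observed-P95 class split near balance
  at 50 Bq/m³ and make the high class a small minority at 600 Bq/m³,
  reproducing the class-imbalance geometry that motivates the balanced
  forest;
* about a quarter of units are measured, with sampling weighted towards
  high-GM geology (surveys oversample areas with known high ambient
  radiation); measurement counts are zero-truncated Poisson (mean 4,
  matching roughly four measurements per measured unit in studies of this
  kind);
* 13 covariates by default: geology plus 7 categorical covariates that
  follow the geology class with probability 0.6, plus 5 continuous
  covariates linear in log latent GM with noise — the last continuous
  covariate is always pure noise so classifier robustness is testable;
* populations are Poisson around 550 per parent (census dissemination areas
  hold 400–700 people); 83 health areas carry uniform smoking prevalences
  (8–25 %);
* deaths are Poisson per unit-year (rate proportional to apportioned
  population; default ~200,000 records over a 16-year window starting
  1998), with sex, age, and an ICD-10-like cause code — a small fraction of
  external-cause (T–Y) and under-20 records exists purely to exercise the
  filters. Among natural adult deaths, the lung cancer probability is
  logistic-linear in the unit's *true* radon stratum (latent
  $P_{95} = \mathrm{GM}\cdot\mathrm{GSD}^{z_{0.95}} \ge 200$ Bq/m³), the
  health area's smoking class, sex and scaled year, with odds-ratio effects
  (defaults 1.5 radon, 1.3 smoking, 1.2 male, no time trend).

Everything derives from one root seed through fixed per-stage substreams,
so a study is reproducible bit for bit.

What the generator does **not** emulate: real geometries (units are grid
cells with jittered centroids, exported as placeholder squares in GeoJSON),
spatially correlated residual radon beyond the regional geology gradient,
measurement seasonality, age structure in mortality, and migration.
Passing tests therefore demonstrate that the pipeline's statistics behave
correctly under a known generating law — not that any particular real
province has recoverable signal of a given size.

## Numerical choices and degenerate inputs

* Quantile convention type 7; single observations pass through.
* Classification ties (votes, leaf majorities, at-threshold $P_{95}$) break
  towards high; the smoking median tie breaks towards lower.
* Categorical covariates are capped at 52 levels (level subsets are stored
  as exact double bitmasks in the serialized trees).
* Zero denominators: accuracy/precision → missing; empty confusion matrix,
  constant Geary values, empty measurement lists → errors.
* CSV output uses fixed 10-significant-digit formatting so file hashes are
  stable across runs and platforms; the pipeline manifest records MD5
  hashes of every artifact.
* Missing covariate values are unsupported (the generator never emits
  them); a missing covariate *column* is a schema error naming the column.

## Problem sizes used in the package's own experiments

The shipped tests and the acceptance script use a province of 2,000 units
(~500 measured), 500 trees per threshold, 999 Geary permutations, and
~200,000 death records; smaller fixtures (100–300 parents, 100–400 trees)
drive the unit tests. These sizes give stable Monte-Carlo behaviour — OOB
kappa well above chance under the default geology–radon signal, generated
mortality odds ratios recovered within a few percent — while a full run of
every stage stays in the tens of seconds on one CPU.

## Known limitations

* Per-threshold models are independent, so predicted maps can violate the
  nesting that the labels obey; the package warns rather than reconciles.
* The eligibility rule is purely categorical; continuous extrapolation
  outside the training range is not flagged.
* No variable importance, probability calibration, or proximity measures;
  no age-standardisation or formal inference on trend differences — the
  pipeline characterises ecologic risk, it does not estimate individual
  dose–response.
* The misclassification sensitivity operation is a deterministic
  count-moving identity; it makes no claim about which decedents were
  misclassified.
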