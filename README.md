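# resadjust

Leakage-free covariate adjustment for cross-validated machine-learning
pipeline search, in R.

## The problem

When features **X** (say, gene expression) and a target **y** (say, a
clinical measurement) are both influenced by covariates — compound, batch,
dose, collection time — any feature–target association found by a model
search may be an artifact of the shared covariate. The classical fix is
residualization: fit a model predicting a variable *v* from the covariates
(linear regression if *v* is continuous, multinomial logistic regression if
it is binary or multiclass ordinal) and replace *v* by its residuals —
either *v* − *v̂* or, for categorical *v* with class codes *c₁…c_K*,
*v* − Σₖ *cₖ p̂ₖ*.

Done naively inside a cross-validated search, residualization **leaks**:
a covariate model fitted on all rows has seen the test rows of every split.
`resadjust` enforces the leakage-free rule — *the covariate model for each
CV split is fitted only on that split's training rows* — for features
(via an in-pipeline residualizing transformer) and for the target (via a
pre-processor that appends, per split, an indicator column and a
precomputed residual-target column, so every downstream estimator can
recover the correct adjusted target for the split it is inside).

On top of that primitive the package provides:

* **Template-constrained evolutionary pipeline search** (`evolve()`):
  genetic programming over pipelines such as
  `FeatureSetSelector-resAdjTransformer-Transformer-Regressor`, where the
  Feature Set Selector restricts features to one named set (e.g. a pathway
  from a GMT file) and the search chooses which.
* **Residual-aware scoring** (`residual_scorer()`): R² computed against the
  split-specific residual target; classic (unadjusted) mode scores
  multiclass targets by balanced accuracy with the identical engine.
* **Permutation importance** (`permutation_importance()`,
  `aggregate_importance()`): per-column mean score decrease on the holdout
  set, aggregated across runs weighted by testing score, as a percentage of
  the score.
* **Covariate-relevance diagnostics** (`kmeans_sweep()`, `dunn_index()`,
  `bhi()`): pick k by the Dunn index, then measure the Biological
  Homogeneity Index of the clustering with respect to each candidate
  covariate — a high BHI flags a covariate the features are structured by.
* **Nominal encoders** (`one_hot_encode()`, `binary_encode()`): drop-first
  dummy coding (N − 1 columns) and compact base-2 coding
  (⌈log₂(N + 1)⌉ columns; 41 categories → 6 columns).
* **A confounded-data simulator** (`simulate_confounded()`,
  `recover_feature_sets()`) with planted ground truth: a *true* feature set
  drives the target, a *decoy* set and the target share a covariate-driven
  confound.

## Worked example

```r
library(resadjust)

sim <- simulate_confounded(sim_config(seed = 1))   # 300 samples, 10 sets x 12 features
ds  <- build_resadj_dataset(sim$table, sim$map, holdout_fraction = 0.25, seed = 1)
search <- evolve(
  ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
  collection = sim$sets, population = 20, generations = 5, seed = 1
)
glance(search)
#> # A tibble: 1 × 8
#>   mode     metric cv_score holdout_score selected_set pipeline     n_evaluations  seed
#>   <chr>    <chr>     <dbl>         <dbl> <chr>        <chr>                <int> <dbl>
#> 1 adjusted r2        0.382         0.350 set01        fss(set_nam…            77     1
```

The search selected `set01` — the planted true set (`sim$truth$true_set`),
whose features drive the target — with a CV R² of 0.38 and holdout R² of
0.35 on the residualized target: the share of the target the planted signal
explains after the covariate-driven confound is removed. The same data
searched *without* adjustment chases the decoy instead:

```r
classic <- evolve(sim$table, "FeatureSetSelector-Transformer-Classifier",
                  collection = sim$sets, population = 20, generations = 5, seed = 1)
glance(classic)$selected_set
#> [1] "set02"      # == sim$truth$decoy_set, driven only by the covariates
```

Importance and diagnostics:

```r
imp <- permutation_importance(search, resadj = ds, n_repeats = 10, seed = 1)
head(aggregate_importance(list(imp)), 3)
#> # A tibble: 3 × 3
#>   column    weighted_pct n_runs_included
#>   <chr>            <dbl>           <int>
#> 1 set01_f10         36.6               1
#> 2 set01_f11         24.6               1
#> 3 set01_f06         20.2               1

bhi(kmeans_sweep(as.matrix(as.data.frame(sim$table)[feature_cols(sim$table)]),
                 2, 8, seed = 1)$best$labels,
    sim$truth$compound)
```

A thin CLI wrapping these functions ships at `inst/scripts/resadj`
(subcommands `preprocess`, `search`, `importance`, `diagnose`, `simulate`).

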