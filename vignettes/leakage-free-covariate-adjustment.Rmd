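---
title: "Leakage-free covariate adjustment for cross-validated pipeline search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-free covariate adjustment for cross-validated pipeline search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resadjust)
```

## The problem

In biomedical tabular data — expression matrices, toxicogenomics panels,
cohort phenotypes — the association between features $X$ and a target $y$
is routinely distorted by covariates: batch, compound, dose, collection
time, demographic structure. The standard remedy is residualization
("regressing out"): fit a model predicting a variable $v$ from the
covariates and replace $v$ by the residuals. For a continuous $v$ the model
is linear regression and the residual is $v_i - \hat v_i$; for a binary or
multiclass-ordinal $v$ the model is multinomial logistic regression and the
residual is the observed value minus the probability-weighted mean of the
class values, $v_i - \sum_k c_k\,\hat p_{ik}$, where $c_k$ are the numeric
class codes.

Inside a cross-validated model search this standard remedy leaks: if the
covariate model is fitted on *all* rows, every training fold has seen
(through the fitted coefficients) the test rows it will later be scored on.
The rule this package enforces is that **the covariate model for each CV
split is fitted only on that split's training rows**, then applied to
training and test rows alike.

Feature adjustment can obey the rule inside a pipeline: a residualizing
transformer fits its covariate models on whatever rows the pipeline is
currently trained on. Target adjustment cannot — by the time an estimator is
fitted, the target it should be fitted *to* depends on which split it is
inside, which generic estimators are never told. The package's solution is a
pre-processing step that materializes the answer in the data itself: for
each of the $S$ predefined splits it appends an **indicator column**
(1 = train, 0 = test, −1 = not in split) and a **residual-target column**
holding the target residualized with a model fitted on that split's training
rows only. One further column holds residuals from a fit on all rows; it is
consulted exactly once, for the final refit after the search has ended. Any
estimator presented with a row subset can then recover "its" target by
matching the subset against the split plan (`identify_split()`), and a
mismatch is an error rather than a silent wrong choice — we consider a loud
failure strictly preferable to scoring against the wrong residuals.

## The search

Pipelines are sequences of typed steps constrained by a template, e.g.
`FeatureSetSelector-resAdjTransformer-Transformer-Regressor`. The Feature
Set Selector restricts the features to one named set (a pathway, in the
expression setting) and the search chooses which; the residualizing
transformer applies per-split feature adjustment and drops the covariate
columns; the remaining steps are ordinary selectors, transformers and
estimators drawn from a compact operator pool.

The optimizer is a small genetic program: an initial population is sampled
uniformly from the template and the hyperparameter grids; variation is
per-step hyperparameter mutation and operator-swap mutation (combined
probability 0.9) plus one-point crossover on step configurations
(probability 0.1); selection is by binary tournament on CV score with
deterministic tie-breaks (higher score, then fewer steps, then earlier
creation) and elitism of one, which makes the best-score trajectory
non-decreasing. Mutation only targets steps that have something to vary
(hyperparameters or alternative operators), so variation is never spent on
no-ops. Pipelines that fail to fit score $-\infty$; a run aborts only if no
valid pipeline exists at all. Evaluations are memoized within a run, and
each pipeline is evaluated under a seed derived from its own configuration,
so memoization cannot change any result.

In *adjusted* mode the target is (residual) continuous and pipelines end in
a regressor scored by $R^2$. In *classic* (unadjusted) mode the same engine
runs with the raw target; a multiclass-ordinal target gets a classifier
template scored by balanced accuracy (the unweighted mean of per-class
recall). Both modes share identical split plans so their outcomes are
directly comparable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_splits`, `scheme` | 5, shuffle | CV splits materialized by the pre-processor |
| `train_fraction` | 0.75 | training share per shuffle split |
| `holdout_fraction` | 0.25 | rows reserved before any split is drawn |
| `population`, `generations` | 20, 5 | GP sizes (desk scale; scale up for real analyses) |
| `ridge` | 1e-4 | penalty on multinomial slopes (not intercepts) |
| `n_repeats` | 10 | shuffles per column in permutation importance |
| `n_init` | 10 | k-means restarts per k in the Dunn sweep |

Whether 5 CV splits should be independent 75/25 shuffles or a 5-fold
partition is genuinely ambiguous in this design space; both are provided and
shuffle is the default. The ordinal residualization uses the ordinal codes
themselves as class values — dose levels 1–4, target septiles 1–7 — since
any other numeric scale would be an unstated modelling choice.

## Numerical choices

* Continuous fits use least squares with intercept; rank-deficient designs
  (collinear encoded covariates are routine) are resolved by the
  minimum-norm SVD solution rather than an error, because a degenerate
  design inside one GP evaluation must not kill a run.
* Categorical residualization is a softmax regression fitted by BFGS with
  analytic gradients and a ridge penalty of 1e-4 on slopes only. The penalty
  guarantees convergence under class separation in small training folds; it
  perturbs fitted probabilities at the 1e-4 scale, which is far below every
  tolerance used in the tests. A training fold containing a single class
  degenerates to predicting that class with probability 1 (residual =
  value − class code), not an error.
* Table round-trips are bit-exact: doubles are written with 17 significant
  digits and parsed with base R's exact `strtod` path.
* Dunn index conventions: all-singleton clusterings give `+Inf` (with a
  warning); the 0/0 case (all points identical) is defined as 0. Ties in the
  k sweep go to the smaller k. `stats::kmeans` (Hartigan–Wong, `n_init`
  restarts) does the clustering; on the rare empty-cluster error the sweep
  retries with a shifted seed rather than failing.
* BHI averages the within-cluster same-annotation pair proportion
  *unweighted over qualifying clusters* (clusters with fewer than 2 members
  are skipped); pooled per-pair weighting is available as an option.
* Balanced accuracy averages recall over the classes observed in the truth
  vector.
* Permutation importance keeps negative decreases (clipping would bias the
  cross-run aggregate); runs with holdout score ≤ 0 are excluded from the
  weighted aggregate and reported, since a non-positive denominator makes
  "percent of score" meaningless.

## What the simulator emulates — and what it does not

`simulate_confounded()` generates the study conditions used throughout the
tests: 300 samples; 10 feature sets of 12 continuous features; a nominal
compound covariate (8 levels, emitted both as labels and as base-2 bit
columns), ordinal dose and time (4 levels each); a confounding signal $h$
that is a standardized seeded linear combination of the encoded covariate
columns; one *true* set whose mean drives the target
(`beta_signal = 2`), one *decoy* set driven by $h$ (`beta_confound = 2`,
noise SD 0.5); and a target that is by default the 7-level septile
discretization of the latent outcome, mirroring an ordinal clinical
measurement. These effect sizes make the confound dominate the unadjusted
analysis (the decoy explains most of the raw target) while leaving the
planted signal clearly recoverable after adjustment — the regime the method
exists for. With `beta_confound = 0` the generator provides the
complementary null in which adjusted and classic searches should agree.

The generator does **not** emulate heavy-tailed expression noise,
probe-level structure, correlated features within sets beyond the shared
confound, missing values, or nonlinear covariate effects. Passing tests
therefore demonstrate the correctness of the adjustment machinery and the
qualitative confounding/recovery contrast, not performance on any real
assay.

Problem sizes in the tests and the acceptance script are chosen for
minutes-scale desk runs: recovery experiments use 20 runs per mode at
population 20 / 5 generations, the oracle-equivalence checks use 200
samples, and the GP fixtures use 90–120 samples with 4 sets of 6 features.
A real analysis would scale the GP sizes and run counts up by one to two
orders of magnitude; nothing in the machinery changes.

## Known limitations

* Residualizing estimators are fixed to linear/multinomial models; trees or
  splines for the adjustment step are out of scope.
* `identify_split()` matches row sets exactly; resampling schemes that
  present rows not matching any planned split (e.g. bootstrapping inside the
  search) are deliberately unsupported.
* No stratified splitting and no nested CV.
* The encoder choice for high-cardinality nominal covariates (one-hot vs
  base-2 binary) materially affects downstream fits and remains the user's
  decision; both encoders are provided with explicit category ordering for
  reproducibility.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_confounded(sim_config(seed = 1))
ds <- build_resadj_dataset(sim$table, sim$map, holdout_fraction = 0.25, seed = 1)
search <- evolve(
  ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
  collection = sim$sets, population = 20, generations = 5, seed = 1
)
glance(search)           # selected set, CV and holdout scores
autoplot(search)         # score trajectory
imp <- permutation_importance(search, resadj = ds, n_repeats = 10, seed = 1)
aggregate_importance(list(imp))
```
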