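Package: resadjust
Title: Leakage-Free Covariate Adjustment for Cross-Validated Pipeline Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residualization-based covariate adjustment for machine-learning
    pipeline optimization that avoids train/test leakage: covariate models are
    fitted on the training rows of each cross-validation split only, and the
    adjusted target for every split is materialized as indicator/residual
    column pairs so any downstream estimator can recover the correct target
    for the split it is inside. Includes template-constrained evolutionary
    pipeline search with feature-set (pathway) selection, permutation-importance
    aggregation across runs, clustering-based covariate-relevance diagnostics
    (Dunn index sweep, Biological Homogeneity Index), nominal-covariate
    encoders, and a generator of confounded expression-like datasets with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
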