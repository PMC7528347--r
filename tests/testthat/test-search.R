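make_search_fixture <- function(m = 90, seed = 5) {
  sim <- simulate_confounded(sim_config(
    m = m, n_sets = 4, set_size = 6, n_compounds = 4,
    target_kind = "continuous", seed = seed
  ))
  ds <- build_resadj_dataset(sim$table, sim$map, holdout_fraction = 0.25, seed = seed)
  list(sim = sim, ds = ds)
}

test_that("templates are validated structurally", {
  expect_length(pipeline_template("FeatureSetSelector-resAdjTransformer-Transformer-Regressor"), 4)
  expect_error(pipeline_template("FeatureSetSelector-Transformer"), "Regressor or Classifier")
  expect_error(pipeline_template("Transformer-resAdjTransformer-Regressor"), "first step")
  expect_error(pipeline_template("Selector-FeatureSetSelector-Regressor"), "first step")
  expect_error(pipeline_template("FeatureSetSelector-Nonsense-Regressor"), "unknown")
})

test_that("feature_set_select restricts features and passes other columns through", {
  fx <- make_search_fixture()
  tab <- fx$ds$table
  out <- feature_set_select(tab, fx$sim$sets, "set02")
  expect_setequal(feature_cols(out), set_members(fx$sim$sets, "set02"))
  expect_setequal(covariate_cols(out), covariate_cols(tab))
  expect_true(all(names(col_roles(tab))[col_roles(tab) == "indicator"] %in% names(out)))

  # intersection semantics: members absent from the table are ignored
  sets2 <- feature_set_collection(list(mix = c("set01_f01", "absent_gene")))
  out2 <- feature_set_select(tab, sets2, "mix")
  expect_equal(feature_cols(out2), "set01_f01")

  sets3 <- feature_set_collection(list(gone = c("nope1", "nope2")))
  expect_error(feature_set_select(tab, sets3, "gone"), "no members")
})

test_that("resadj_transform fit+transform matches adjust_for_split on the same rows", {
  tab <- random_table(50, 4, 2, seed = 66)
  covs <- c("c1", "c2")
  map <- adjustment_map(stats::setNames(rep(list(covs), 4), paste0("f", 1:4)))
  train <- 1:35
  sub <- resadjust:::set_table_meta(
    tibble::as_tibble(as.data.frame(tab))[train, ], col_roles(tab), col_kinds(tab)
  )
  fitted <- resadj_transform(sub, map, context = "fit")
  # covariates dropped, features residualized
  expect_length(covariate_cols(fitted$table), 0)
  oracle <- adjust_for_split(tab, map, list(train = train, test = integer(0)))
  for (col in paste0("f", 1:4)) {
    expect_equal(fitted$table[[col]], oracle[[col]][train], tolerance = 1e-10)
  }
  # transform context: test rows residualized with train-fitted models
  test_rows <- 36:50
  sub_test <- resadjust:::set_table_meta(
    tibble::as_tibble(as.data.frame(tab))[test_rows, ], col_roles(tab), col_kinds(tab)
  )
  transformed <- resadj_transform(sub_test, map, context = "transform", models = fitted$models)
  oracle2 <- adjust_for_split(tab, map, list(train = train, test = test_rows))
  for (col in paste0("f", 1:4)) {
    expect_equal(transformed$table[[col]], oracle2[[col]][test_rows], tolerance = 1e-10)
  }
  expect_error(resadj_transform(sub_test, map, context = "transform"), "prior fit")
})

test_that("resadj_transform with an empty map only drops covariates", {
  tab <- random_table(20, 3, 2, seed = 7)
  out <- resadj_transform(tab, adjustment_map(), context = "fit")
  expect_length(covariate_cols(out$table), 0)
  for (col in paste0("f", 1:3)) expect_identical(out$table[[col]], tab[[col]])
})

test_that("residual_scorer computes R2 against the split's residual column", {
  fx <- make_search_fixture()
  ds <- fx$ds
  s <- ds$plan$splits[[2]]
  res <- ds$table[["__split2_residual"]][s$test]
  expect_equal(residual_scorer(ds, res, s$test, metric = "r2"), 1)
  expect_equal(residual_scorer(ds, rep(mean(res), length(res)), s$test, metric = "r2"), 0)
  # hand-sized brute-force check on four rows
  obs <- c(1, -1, 2, -2)
  pred <- c(0.5, -0.5, 1, -1)
  expect_equal(
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
    0.75
  )
  ds$table[["__split2_residual"]][s$test[1:4]] <- obs
  expect_equal(
    residual_scorer(ds, c(pred, res[-(1:4)]), s$test, metric = "r2"),
    1 - sum((obs - pred)^2) / sum((c(obs, res[-(1:4)]) - mean(c(obs, res[-(1:4)])))^2)
  )
})

test_that("balanced accuracy equals the mean of per-class recalls", {
  # confusion: class 1 -> 2/3 right, class 2 -> 1/2, class 3 -> 1
  truth <- c(1, 1, 1, 2, 2, 3)
  pred <- c(1, 1, 2, 2, 3, 3)
  expect_equal(balanced_accuracy(truth, pred), mean(c(2 / 3, 1 / 2, 1)))
  expect_equal(balanced_accuracy(truth, truth), 1)
})

test_that("a degenerate search (population 1, generations 0) returns that pipeline CV-scored", {
  fx <- make_search_fixture()
  pool <- default_operator_pool(fx$sim$sets)
  # single-choice pool with fixed hyperparameters
  pool$FeatureSetSelector$fss$params$set_name <- "set01"
  pool$Transformer <- pool$Transformer["standard_scaler"]
  pool$Regressor <- pool$Regressor["linear_reg"]
  s <- evolve(fx$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
    collection = fx$sim$sets, pool = pool, population = 1, generations = 0, seed = 3
  )
  expect_equal(glance(s)$selected_set, "set01")
  expect_equal(s$n_evaluations, 1)
  expect_true(is.finite(s$best$cv_score))
  # the CV score is the mean over splits of the brute-force evaluation
  manual <- mean(vapply(seq_along(fx$ds$plan$splits), function(i) {
    sp <- fx$ds$plan$splits[[i]]
    at <- adjust_for_split(fx$ds$table, fx$sim$map, sp)
    X <- as.matrix(as.data.frame(at)[, set_members(fx$sim$sets, "set01")])
    X <- scale(X, center = colMeans(X[sp$train, ]), scale = apply(X[sp$train, ], 2, sd))
    y <- fx$ds$table[[sprintf("__split%d_residual", i)]]
    b <- qr.solve(cbind(1, X[sp$train, ]), y[sp$train])
    pred <- drop(cbind(1, X[sp$test, ]) %*% b)
    1 - sum((y[sp$test] - pred)^2) / sum((y[sp$test] - mean(y[sp$test]))^2)
  }, numeric(1)))
  expect_equal(s$best$cv_score, manual, tolerance = 1e-8)
})

test_that("the same seed reproduces the generation log exactly", {
  fx <- make_search_fixture()
  s1 <- evolve(fx$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
    collection = fx$sim$sets, population = 8, generations = 3, seed = 11
  )
  fx2 <- make_search_fixture()
  s2 <- evolve(fx2$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
    collection = fx2$sim$sets, population = 8, generations = 3, seed = 11
  )
  expect_identical(s1$log, s2$log)
  expect_identical(format(s1$best), format(s2$best))
})

test_that("elitism makes the best score non-decreasing across generations", {
  fx <- make_search_fixture(seed = 17)
  s <- evolve(fx$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
    collection = fx$sim$sets, population = 10, generations = 5, seed = 29
  )
  expect_true(all(diff(s$log$best_score) >= 0))
})

test_that("the search recovers a planted linearly-predictive feature set", {
  # the true set linearly determines the residual target; the exhaustive
  # oracle (per-set linear CV R2) confirms it is optimal, and the GP should
  # find it in nearly every seeded run
  fx <- make_search_fixture(m = 120, seed = 19)
  oracle_best <- {
    scores <- vapply(fx$sim$sets$set_name, function(sn) {
      mean(vapply(seq_along(fx$ds$plan$splits), function(i) {
        sp <- fx$ds$plan$splits[[i]]
        at <- adjust_for_split(fx$ds$table, fx$sim$map, sp)
        X <- as.matrix(as.data.frame(at)[, set_members(fx$sim$sets, sn)])
        y <- fx$ds$table[[sprintf("__split%d_residual", i)]]
        b <- qr.solve(cbind(1, X[sp$train, ]), y[sp$train])
        pred <- drop(cbind(1, X[sp$test, ]) %*% b)
        1 - sum((y[sp$test] - pred)^2) / sum((y[sp$test] - mean(y[sp$test]))^2)
      }, numeric(1)))
    }, numeric(1))
    names(which.max(scores))
  }
  expect_equal(oracle_best, fx$sim$truth$true_set)
  hits <- vapply(1:20, function(r) {
    s <- evolve(fx$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
      collection = fx$sim$sets, population = 20, generations = 5, seed = 100 + r
    )
    glance(s)$selected_set == fx$sim$truth$true_set
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("holdout scoring works and a perfect-prediction pipeline scores 1", {
  fx <- make_search_fixture(seed = 23)
  s <- evolve(fx$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
    collection = fx$sim$sets, population = 10, generations = 2, seed = 31
  )
  expect_true(is.numeric(s$best$holdout_score))
  expect_equal(
    holdout_score(s, fx$ds),
    {
      preds <- predict(s, fx$ds$holdout$table)
      obs <- fx$ds$holdout$residual_target
      1 - sum((obs - preds)^2) / sum((obs - mean(obs))^2)
    }
  )
  # R2 of 1 for exact predictions, <= 0 for a constant at the holdout mean or worse
  obs <- fx$ds$holdout$residual_target
  expect_equal(resadjust:::r_squared(obs, obs), 1)
  expect_lte(resadjust:::r_squared(obs, rep(mean(obs) + 1, length(obs))), 0)
})

test_that("no component inside the search consults the full-data residual column", {
  fx <- make_search_fixture(seed = 37)
  s <- evolve(fx$ds, "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
    collection = fx$sim$sets, population = 8, generations = 3, seed = 41
  )
  log <- fx$ds$lookup_log
  full_seqs <- vapply(
    Filter(function(cl) identical(cl$split, "FULL"), log$calls),
    `[[`, integer(1), "seq"
  )
  expect_gt(length(full_seqs), 0) # the final refit does use it
  expect_true(all(full_seqs > log$search_end))
})

test_that("classic mode runs the identical engine with a classifier template", {
  sim <- simulate_confounded(sim_config(
    m = 90, n_sets = 4, set_size = 6, n_compounds = 4,
    target_kind = "ordinal7", seed = 53
  ))
  s <- evolve(sim$table, "FeatureSetSelector-Transformer-Classifier",
    collection = sim$sets, population = 10, generations = 2, seed = 3
  )
  expect_equal(s$mode, "classic")
  expect_equal(s$metric, "balanced_accuracy")
  expect_true(is.finite(s$best$cv_score))
  # under strong confounding the decoy set dominates the unadjusted search
  expect_equal(glance(s)$selected_set, sim$truth$decoy_set)
})
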