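test_that("shuffle plans have the requested sizes and are seed-reproducible", {
  plan <- make_split_plan(100, n_splits = 5, scheme = "shuffle", train_fraction = 0.75, seed = 7)
  expect_length(plan$splits, 5)
  for (s in plan$splits) {
    expect_length(s$train, 75)
    expect_length(s$test, 25)
    expect_length(intersect(s$train, s$test), 0)
  }
  plan2 <- make_split_plan(100, n_splits = 5, scheme = "shuffle", train_fraction = 0.75, seed = 7)
  expect_identical(plan, plan2)
  plan3 <- make_split_plan(100, n_splits = 5, scheme = "shuffle", train_fraction = 0.75, seed = 8)
  expect_false(identical(plan$splits, plan3$splits))
})

test_that("kfold test sets partition the rows", {
  plan <- make_split_plan(10, n_splits = 5, scheme = "kfold", seed = 1)
  tests <- lapply(plan$splits, `[[`, "test")
  expect_true(all(lengths(tests) == 2))
  expect_setequal(unlist(tests), 1:10)
  expect_equal(sum(lengths(tests)), 10)
  expect_error(make_split_plan(4, n_splits = 5, scheme = "kfold"), "exceeds")
})

test_that("split plans round-trip through the sidecar CSV", {
  plan <- make_split_plan(30, n_splits = 4, scheme = "shuffle", seed = 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  expect_equal(back$splits, plan$splits)
  expect_equal(back$scheme, plan$scheme)
  expect_equal(back$seed, plan$seed)
})

test_that("build_resadj_dataset appends 2 columns per split plus a full-residual column", {
  tab <- random_table(60, 3, 2, seed = 15)
  map <- adjustment_map(list(f1 = c("c1", "c2")), target_covariates = c("c1", "c2"))
  ds <- build_resadj_dataset(tab, map, seed = 4)
  added <- setdiff(names(ds$table), names(tab))
  expect_length(added, 11) # 5 indicators + 5 residuals + full residual
  roles <- col_roles(ds$table)
  expect_equal(sum(roles == "indicator"), 5)
  expect_equal(sum(roles == "residual_target"), 6)
  for (i in 1:5) {
    ind <- ds$table[[sprintf("__split%d_indicator", i)]]
    res <- ds$table[[sprintf("__split%d_residual", i)]]
    expect_true(all(ind %in% c(-1L, 0L, 1L)))
    expect_identical(which(ind == 1L), ds$plan$splits[[i]]$train)
    expect_identical(which(ind == 0L), ds$plan$splits[[i]]$test)
    expect_true(all(is.na(res) == (ind == -1L)))
  }
  expect_false(anyNA(ds$table[["__full_residual"]]))
})

test_that("per-split residual columns equal models fit on exactly those train rows", {
  tab <- random_table(80, 2, 3, seed = 55)
  covs <- paste0("c", 1:3)
  map <- adjustment_map(list(f1 = covs), target_covariates = covs)
  ds <- build_resadj_dataset(tab, map, seed = 12)
  for (i in seq_along(ds$plan$splits)) {
    s <- ds$plan$splits[[i]]
    expected <- oracle_residuals_continuous(tab$y, tab[covs], s$train, sort(union(s$train, s$test)))
    got <- ds$table[[sprintf("__split%d_residual", i)]][sort(union(s$train, s$test))]
    expect_equal(got, unname(expected), tolerance = 1e-8)
  }
  full_expected <- oracle_residuals_continuous(tab$y, tab[covs], 1:80, 1:80)
  expect_equal(ds$table[["__full_residual"]], unname(full_expected), tolerance = 1e-8)
})

test_that("holdout rows are excluded from every split and every fitted model", {
  tab <- random_table(100, 2, 2, seed = 23)
  covs <- c("c1", "c2")
  map <- adjustment_map(list(f1 = covs), target_covariates = covs)
  ds <- build_resadj_dataset(tab, map, holdout_fraction = 0.25, seed = 6)
  expect_length(ds$holdout$rows, 25)
  expect_equal(nrow(ds$table), 75)
  expect_length(ds$holdout$residual_target, 25)
  # perturbing holdout-row values changes nothing in the augmented table
  tab2 <- tab
  tab2$y[ds$holdout$rows] <- tab2$y[ds$holdout$rows] + 50
  tab2 <- resadjust:::set_table_meta(tab2, col_roles(tab), col_kinds(tab))
  ds2 <- build_resadj_dataset(tab2, map, holdout_fraction = 0.25, seed = 6)
  expect_identical(
    as.data.frame(ds$table)[startsWith(names(ds$table), "__")],
    as.data.frame(ds2$table)[startsWith(names(ds2$table), "__")]
  )
  # holdout target residualized by the full non-holdout fit
  expected <- {
    fit <- stats::lm(y ~ c1 + c2, data = as.data.frame(tab)[-ds$holdout$rows, ])
    tab$y[ds$holdout$rows] -
      stats::predict(fit, newdata = as.data.frame(tab)[ds$holdout$rows, ])
  }
  expect_equal(ds$holdout$residual_target, unname(expected), tolerance = 1e-8)
})

test_that("rebuilding with the same seed is bit-identical", {
  tab <- random_table(50, 2, 2, seed = 2)
  map <- adjustment_map(list(f1 = "c1"), target_covariates = c("c1", "c2"))
  ds1 <- build_resadj_dataset(tab, map, holdout_fraction = 0.2, seed = 33)
  ds2 <- build_resadj_dataset(tab, map, holdout_fraction = 0.2, seed = 33)
  expect_identical(as.data.frame(ds1$table), as.data.frame(ds2$table))
  expect_identical(ds1$holdout$residual_target, ds2$holdout$residual_target)
})

test_that("a map without target covariates is rejected with workflow guidance", {
  tab <- random_table(30, 2, 2, seed = 3)
  expect_error(
    build_resadj_dataset(tab, adjustment_map(list(f1 = "c1")), seed = 1),
    "feature-only"
  )
})

test_that("identify_split matches train/test/full row sets and flags ambiguity", {
  tab <- random_table(40, 2, 2, seed = 44)
  map <- adjustment_map(list(f1 = "c1"), target_covariates = "c1")
  ds <- build_resadj_dataset(tab, map, seed = 9)
  s3 <- ds$plan$splits[[3]]
  expect_equal(identify_split(ds, s3$train), list(split = 3, context = "fitting"))
  expect_equal(identify_split(ds, s3$test), list(split = 3, context = "scoring"))
  expect_equal(identify_split(ds, 1:40)$split, "FULL")
  # an arbitrary half matching no split
  expect_error(identify_split(ds, 1:20), "cannot identify")
  # lookups were instrumented
  contexts <- vapply(ds$lookup_log$calls, `[[`, character(1), "context")
  expect_equal(contexts, c("fitting", "scoring", "full"))
})
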