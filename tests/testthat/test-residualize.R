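test_that("intercept-only continuous model predicts the training mean", {
  v <- c(1, 2, 3, 10)
  m <- fit_residual_model(v, C = NULL, rows = 1:3, kind = "continuous")
  expect_equal(residuals(m, v = v, rows = 1:3), c(-1, 0, 1))
  # applied to an unseen row: still the training mean
  expect_equal(residuals(m, v = v, rows = 4), 10 - 2)
})

test_that("a perfectly explanatory covariate gives slope 1, intercept 0, zero residuals", {
  withr::with_seed(5, {
    c1 <- rnorm(30)
    v <- c1
    C <- cbind(c1 = c1)
    m <- fit_residual_model(v, C, rows = 1:20, kind = "continuous")
    expect_equal(unname(m$coef), c(0, 1), tolerance = 1e-10)
    expect_true(all(abs(residuals(m, v = v, C = C, rows = 1:30)) < 1e-8))
  })
})

test_that("saturated binary model recovers empirical cell proportions", {
  # cells: c=0 -> v in {0,0,1}; c=1 -> v in {1,1,0}
  v <- c(0, 0, 1, 1, 1, 0)
  C <- cbind(c = c(0, 0, 0, 1, 1, 1))
  m <- fit_residual_model(v, C, rows = 1:6, kind = "binary")
  p <- class_probabilities(m, C)
  # oracle: direct cell proportions (tiny ridge shifts them by ~1e-4)
  expect_equal(unname(p[1, "1"]), 1 / 3, tolerance = 5e-4)
  expect_equal(unname(p[4, "1"]), 2 / 3, tolerance = 5e-4)
  # expected-value residual on a test row (c=0, v=1) with class values {0,1}
  expect_equal(
    residuals(m, v = c(1), C = cbind(c = 0), rows = 1),
    1 - unname(p[1, "1"])
  )
})

test_that("single-class training fold degenerates to constant probability 1", {
  v <- c(2, 2, 2, 5, 2)
  C <- cbind(c = rnorm(5))
  m <- fit_residual_model(v, C, rows = 1:3, kind = "ordinal")
  expect_true(m$degenerate)
  expect_equal(residuals(m, v = v, C = C, rows = 1:5), v - 2)
})

test_that("ordinal expected-value residuals use the class codes themselves", {
  withr::with_seed(8, {
    n <- 120
    c1 <- rnorm(n)
    latent <- 1.5 * c1 + rnorm(n, sd = 0.5)
    v <- as.numeric(cut(latent, breaks = c(-Inf, -1, 1, Inf), labels = FALSE))
    C <- cbind(c1 = c1)
    m <- fit_residual_model(v, C, rows = 1:n, kind = "ordinal")
    expect_equal(sort(m$class_values), c(1, 2, 3))
    P <- class_probabilities(m, C)
    expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
    r <- residuals(m, v = v, C = C, rows = seq_len(n))
    expect_equal(r, v - drop(P %*% m$class_values), tolerance = 1e-12)
    # regressing out a strong driver shrinks variance
    expect_lt(stats::var(r), stats::var(v))
  })
})

test_that("rank-deficient continuous designs are handled by the minimum-norm solution", {
  withr::with_seed(13, {
    c1 <- rnorm(20)
    C <- cbind(c1 = c1, c2 = c1) # perfectly collinear
    v <- 2 * c1 + rnorm(20, sd = 0.1)
    m <- fit_residual_model(v, C, rows = 1:20, kind = "continuous")
    expect_true(all(is.finite(m$coef)))
    # predictions match an ordinary single-covariate fit
    m1 <- fit_residual_model(v, C[, 1, drop = FALSE], rows = 1:20, kind = "continuous")
    expect_equal(
      predict(m, v = v, C = C, rows = 1:20),
      predict(m1, v = v, C = C[, 1, drop = FALSE], rows = 1:20),
      tolerance = 1e-8
    )
  })
})

test_that("adjust_for_split with an empty map returns the table unchanged", {
  tab <- tiny_table()
  out <- adjust_for_split(tab, adjustment_map(), list(train = 1:4, test = 5:6))
  expect_identical(as.data.frame(out), as.data.frame(tab))
})

test_that("adjust_for_split equals a hand OLS fit on the training rows", {
  tab <- tiny_table(m = 6, seed = 3)
  split <- list(train = 1:4, test = 5:6)
  map <- adjustment_map(list(g1 = "c1"))
  out <- adjust_for_split(tab, map, split)
  expected <- oracle_residuals_continuous(tab$g1, tab["c1"], split$train, 1:6)
  expect_equal(out$g1, unname(expected), tolerance = 1e-10)
  # unmapped columns untouched
  expect_identical(out$g2, tab$g2)
  expect_identical(out$c1, tab$c1)
})

test_that("no leakage: train-row residuals are bit-invariant to test-row perturbations", {
  tab <- random_table(40, 3, 2, seed = 21)
  split <- list(train = 1:30, test = 31:40)
  map <- adjustment_map(list(f1 = c("c1", "c2"), f2 = "c1"), target_covariates = c("c1", "c2"))
  out1 <- adjust_for_split(tab, map, split)
  # perturb test-row values of the adjusted variables and the covariates
  tab2 <- tab
  for (col in c("f1", "f2", "y", "c1", "c2")) {
    tab2[[col]][split$test] <- tab2[[col]][split$test] + 100 * seq_along(split$test)
  }
  tab2 <- resadjust:::set_table_meta(tab2, col_roles(tab), col_kinds(tab))
  out2 <- adjust_for_split(tab2, map, split)
  for (col in c("f1", "f2", "y")) {
    expect_identical(out1[[col]][split$train], out2[[col]][split$train], label = col)
  }
})

test_that("train-row residuals are orthogonal to covariates (mean 0, zero covariance)", {
  tab <- random_table(100, 4, 3, seed = 31)
  split <- list(train = 1:75, test = 76:100)
  covs <- c("c1", "c2", "c3")
  map <- adjustment_map(
    stats::setNames(rep(list(covs), 4), paste0("f", 1:4)),
    target_covariates = covs
  )
  out <- adjust_for_split(tab, map, split)
  for (col in c(paste0("f", 1:4), "y")) {
    r <- out[[col]][split$train]
    expect_lt(abs(mean(r)), 1e-8)
    for (cv in covs) {
      centered <- tab[[cv]][split$train] - mean(tab[[cv]][split$train])
      expect_lt(abs(sum(r * centered) / (length(r) - 1)), 1e-8)
    }
  }
})

test_that("split-fit residuals differ from whole-data-fit residuals on test rows", {
  tab <- random_table(60, 2, 2, seed = 77)
  split <- list(train = 1:45, test = 46:60)
  map <- adjustment_map(list(f1 = c("c1", "c2")))
  split_fit <- adjust_for_split(tab, map, split)
  full_fit <- adjust_for_split(tab, map, list(train = 1:60, test = integer(0)))
  expect_false(all(abs(split_fit$f1[split$test] - full_fit$f1[split$test]) < 1e-6))
})

test_that("adjust_for_split matches the brute-force oracle on a random table", {
  tab <- random_table(200, 5, 3, seed = 101)
  covs <- paste0("c", 1:3)
  map <- adjustment_map(
    stats::setNames(rep(list(covs), 5), paste0("f", 1:5)),
    target_covariates = covs
  )
  plan <- make_split_plan(200, n_splits = 5, scheme = "shuffle", seed = 202)
  for (s in plan$splits) {
    out <- adjust_for_split(tab, map, s)
    rows <- sort(union(s$train, s$test))
    for (col in c(paste0("f", 1:5), "y")) {
      expected <- oracle_residuals_continuous(tab[[col]], tab[covs], s$train, rows)
      expect_equal(out[[col]][rows], unname(expected), tolerance = 1e-8)
    }
  }
})
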