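# Small in-code fixtures shared across tests.

tiny_table <- function(m = 6, seed = 42) {
  withr::with_seed(seed, {
    adjusted_table(
      tibble::tibble(
        sample_id = sprintf("s%d", seq_len(m)),
        g1 = rnorm(m), g2 = rnorm(m), g3 = rnorm(m),
        c1 = rnorm(m), c2 = sample(0:1, m, replace = TRUE),
        y = rnorm(m)
      ),
      roles = c(g1 = "feature", g2 = "feature", g3 = "feature",
                c1 = "covariate", c2 = "covariate", y = "target"),
      kinds = c(g1 = "continuous", g2 = "continuous", g3 = "continuous",
                c1 = "continuous", c2 = "binary", y = "continuous")
    )
  })
}

random_table <- function(m, n_features, n_covariates, seed) {
  withr::with_seed(seed, {
    feats <- matrix(rnorm(m * n_features), m,
      dimnames = list(NULL, sprintf("f%d", seq_len(n_features)))
    )
    covs <- matrix(rnorm(m * n_covariates), m,
      dimnames = list(NULL, sprintf("c%d", seq_len(n_covariates)))
    )
    y <- rnorm(m) + 0.5 * covs[, 1]
    data <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%d", seq_len(m))),
      tibble::as_tibble(feats), tibble::as_tibble(covs),
      tibble::tibble(y = y)
    )
    adjusted_table(data,
      roles = c(
        stats::setNames(rep("feature", n_features), colnames(feats)),
        stats::setNames(rep("covariate", n_covariates), colnames(covs)),
        y = "target"
      ),
      kinds = c(
        stats::setNames(rep("continuous", n_features), colnames(feats)),
        stats::setNames(rep("continuous", n_covariates), colnames(covs)),
        y = "continuous"
      )
    )
  })
}

# brute-force residualization oracle: fit on train, predict, subtract;
# intentionally independent of the package's residualization code path
oracle_residuals_continuous <- function(v, C, train, rows) {
  df <- as.data.frame(C)
  fit <- stats::lm(v ~ ., data = cbind(df, v = v), subset = train)
  v[rows] - stats::predict(fit, newdata = df[rows, , drop = FALSE])
}
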