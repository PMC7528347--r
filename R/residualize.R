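#' Fit a covariate model for one variable on training rows only
#'
#' "Regressing covariates out" of a variable `v` means fitting a model
#' predicting `v` from the covariates and replacing `v` by the residuals.
#' The leakage-free rule is that, within a CV split, the model is fitted
#' *only on that split's training rows*, then applied to training and test
#' rows alike; this function does the fitting half and records which rows it
#' saw.
#'
#' Continuous variables use least squares with intercept (rank-deficient
#' designs are resolved by the minimum-norm solution, so collinear encoded
#' covariates never fail). Binary and multiclass-ordinal variables use
#' multinomial logistic regression with a small ridge penalty (`ridge`, on
#' slopes, not intercepts) that guarantees convergence under class
#' separation; residuals are then the observed value minus the
#' probability-weighted mean of the class values. If the training rows
#' contain a single class, the model degenerates to predicting that class
#' with probability 1.
#'
#' @param v Numeric vector (full length; only `rows` are used for fitting).
#' @param C Covariate matrix or data frame with named numeric columns; may
#'   have zero columns (intercept-only model).
#' @param rows Integer vector of training row indices.
#' @param kind `"continuous"`, `"binary"` or `"ordinal"`.
#' @param ridge Ridge penalty on multinomial slopes (default `1e-4`).
#' @return An object of class `residual_model`.
#' @examples
#' v <- c(1, 2, 3, 10)
#' m <- fit_residual_model(v, C = NULL, rows = 1:3, kind = "continuous")
#' residuals(m, v = v, C = NULL, rows = 1:3) # v - mean(v[1:3])
#' @export
fit_residual_model <- function(v, C, rows, kind = c("continuous", "binary", "ordinal"),
                               ridge = 1e-4) {
  kind <- match.arg(kind)
  if (length(rows) == 0) abort("training row set is empty")
  C <- as_covariate_matrix(C, length(v))
  vt <- v[rows]
  Xt <- cbind(`(Intercept)` = 1, C[rows, , drop = FALSE])
  if (kind == "continuous") {
    coef <- lstsq_min_norm(Xt, vt)
    model <- list(kind = kind, covariate_names = colnames(C), fit_rows = rows,
                  coef = drop(coef))
  } else {
    class_values <- sort(unique(vt))
    if (kind == "binary" && length(class_values) > 2) {
      abort("variable declared binary has more than 2 levels on training rows")
    }
    if (length(class_values) == 1) {
      model <- list(kind = kind, covariate_names = colnames(C), fit_rows = rows,
                    class_values = class_values, degenerate = TRUE, B = NULL)
    } else {
      B <- fit_multinomial_ridge(vt, Xt, class_values, ridge)
      model <- list(kind = kind, covariate_names = colnames(C), fit_rows = rows,
                    class_values = class_values, degenerate = FALSE, B = B)
    }
  }
  structure(model, class = "residual_model")
}

as_covariate_matrix <- function(C, m) {
  if (is.null(C) || (is.data.frame(C) && ncol(C) == 0)) {
    return(matrix(numeric(0), nrow = m, ncol = 0))
  }
  C <- as.matrix(C)
  if (!is.numeric(C)) abort("covariate columns must be numeric")
  C
}

# Ridge-penalized multinomial logistic regression (softmax), reference =
# first class; penalty on slopes only. Fitted by BFGS with analytic gradient.
fit_multinomial_ridge <- function(y, X, class_values, ridge) {
  K <- length(class_values)
  p1 <- ncol(X)
  Y <- outer(y, class_values, `==`) * 1 # m x K one-hot
  obj <- function(par) {
    B <- matrix(par, p1, K - 1)
    P <- softmax_rows(cbind(0, X %*% B))
    -sum(log(pmax(rowSums(P * Y), 1e-300))) + ridge * sum(B[-1, ]^2)
  }
  grad <- function(par) {
    B <- matrix(par, p1, K - 1)
    P <- softmax_rows(cbind(0, X %*% B))
    G <- crossprod(X, P[, -1, drop = FALSE] - Y[, -1, drop = FALSE])
    G[-1, ] <- G[-1, ] + 2 * ridge * B[-1, ]
    as.vector(G)
  }
  fit <- stats::optim(rep(0, p1 * (K - 1)), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  matrix(fit$par, p1, K - 1, dimnames = list(colnames(X), NULL))
}

#' @describeIn fit_residual_model Predicted values (continuous) or
#'   class-probability expected values (categorical) for the given rows.
#' @param object,model A `residual_model`.
#' @export
predict.residual_model <- function(object, v = NULL, C = NULL, rows = NULL, ...) {
  m <- if (!is.null(v)) length(v) else nrow(as.matrix(C))
  C <- as_covariate_matrix(C, m)
  missing_cov <- setdiff(object$covariate_names, colnames(C))
  if (length(missing_cov) > 0) {
    abort(sprintf("covariate column(s) missing: %s", toString(missing_cov)))
  }
  rows <- rows %||% seq_len(nrow(C))
  X <- cbind(`(Intercept)` = 1, C[rows, object$covariate_names, drop = FALSE])
  if (object$kind == "continuous") {
    return(drop(X %*% object$coef))
  }
  if (isTRUE(object$degenerate)) {
    return(rep(object$class_values, length(rows)))
  }
  P <- softmax_rows(cbind(0, X %*% object$B))
  drop(P %*% object$class_values)
}

#' @describeIn fit_residual_model Class-probability matrix (categorical
#'   kinds), columns ordered by `class_values`.
#' @export
class_probabilities <- function(model, C, rows = NULL) {
  stopifnot(model$kind != "continuous")
  C <- as_covariate_matrix(C, nrow(as.matrix(C)))
  rows <- rows %||% seq_len(nrow(C))
  if (isTRUE(model$degenerate)) {
    return(matrix(1, length(rows), 1, dimnames = list(NULL, model$class_values)))
  }
  X <- cbind(`(Intercept)` = 1, C[rows, model$covariate_names, drop = FALSE])
  P <- softmax_rows(cbind(0, X %*% model$B))
  colnames(P) <- model$class_values
  P
}

#' @describeIn fit_residual_model Residuals of `v` over `rows`: observed
#'   minus predicted (continuous) or minus the expected class value
#'   (categorical). `rows` may include rows outside the model's training
#'   rows — that is the point of leakage-free adjustment.
#' @param ... Unused.
#' @export
residuals.residual_model <- function(object, v, C = NULL, rows = NULL, ...) {
  rows <- rows %||% seq_along(v)
  v[rows] - predict(object, v = v, C = C, rows = rows)
}

#' Residualize mapped columns for one train/test split
#'
#' For every variable in the adjustment map (features, and the target when
#' the map adjusts it), fits a covariate model on the split's training rows
#' only and replaces the variable's values over train-and-test rows by the
#' residuals. Unmapped columns and the covariate columns themselves are left
#' untouched; rows outside the split keep their original values. Adjusted
#' columns become kind `continuous`.
#'
#' Continuous variables sharing a covariate set are fitted in one
#' multi-response least-squares solve — a pure speed optimization with
#' identical results to per-column fits.
#'
#' @param table An [adjusted_table].
#' @param map An [adjustment_map].
#' @param split A `list(train, test)` of row indices (one element of a
#'   [make_split_plan()] plan).
#' @param ridge Ridge penalty passed to categorical fits.
#' @return The table with mapped columns replaced by residuals on
#'   `union(train, test)` rows.
#' @export
adjust_for_split <- function(table, map, split, ridge = 1e-4) {
  if (nrow(map) == 0 && !adjusts_target(map)) {
    return(table)
  }
  validate_adjustment_map(map, table)
  rows_all <- sort(union(split$train, split$test))
  if (max(rows_all) > nrow(table)) abort("split references rows beyond the table")
  kinds <- col_kinds(table)
  roles <- col_roles(table)
  entries <- tibble(variable = map$variable, covariates = map$covariates)
  if (adjusts_target(map)) {
    tc <- target_col(table)
    if (is.null(tc)) abort("map adjusts the target but the table has no target column")
    entries <- dplyr::bind_rows(entries, tibble(variable = tc, covariates = list(target_covariates(map))))
  }
  entries$kind <- unname(kinds[entries$variable])
  if (any(entries$kind == "nominal")) {
    abort("nominal columns must be encoded before residualization")
  }
  out <- as_tibble(as.data.frame(table))
  # continuous variables grouped by covariate set -> one multi-response solve
  cont <- entries[entries$kind == "continuous", ]
  if (nrow(cont) > 0) {
    key <- vapply(cont$covariates, function(cv) paste(cv, collapse = "\r"), character(1))
    for (k in unique(key)) {
      grp <- cont[key == k, ]
      covs <- grp$covariates[[1]]
      X <- cbind(1, as.matrix(out[covs])) # zero covariates -> intercept only
      V <- as.matrix(out[grp$variable])
      coef <- lstsq_min_norm(X[split$train, , drop = FALSE], V[split$train, , drop = FALSE])
      res <- V[rows_all, , drop = FALSE] - X[rows_all, , drop = FALSE] %*% coef
      for (j in seq_along(grp$variable)) {
        out[[grp$variable[j]]][rows_all] <- res[, j]
      }
    }
  }
  for (i in which(entries$kind != "continuous")) {
    var <- entries$variable[i]
    covs <- entries$covariates[[i]]
    model <- fit_residual_model(out[[var]], out[covs], split$train,
      kind = entries$kind[i], ridge = ridge
    )
    out[[var]][rows_all] <- residuals(model, v = out[[var]], C = out[covs], rows = rows_all)
  }
  kinds[entries$variable] <- "continuous"
  set_table_meta(out, roles, kinds)
}
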