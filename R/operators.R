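# Operator registry for the pipeline search.
#
# Every operator is a list with: id, role, params (named list of candidate
# value grids), fit(M, y, params, ctx, rows) -> state, and transform(state,
# M) (selectors/transformers) or predict(state, M) (estimators). M is a
# numeric matrix with column names over the rows the step currently sees;
# ctx carries table-level metadata (covariate names, kinds, adjustment map,
# residualization cache). All default operators are deterministic and
# RNG-free so search runs are reproducible.

op_registry <- function() {
  list(
    FeatureSetSelector = list(
      fss = list(
        id = "fss", role = "FeatureSetSelector",
        params = list(set_name = NULL), # grid filled from the collection
        fit = function(M, y, params, ctx, rows) {
          members <- set_members(ctx$collection, params$set_name)
          feats <- setdiff(colnames(M), ctx$covariate_names)
          sel <- intersect(members, feats)
          if (length(sel) == 0) {
            abort(sprintf("feature set '%s' has no members in the table", params$set_name))
          }
          c(sel, intersect(ctx$covariate_names, colnames(M)))
        },
        transform = function(state, M) M[, intersect(state, colnames(M)), drop = FALSE]
      )
    ),
    resAdjTransformer = list(
      resadj_transformer = list(
        id = "resadj_transformer", role = "resAdjTransformer",
        params = list(),
        fit = function(M, y, params, ctx, rows) {
          fit_feature_residualizers(ctx, rows)
        },
        transform = function(state, M) apply_feature_residualizers(state, M)
      )
    ),
    Selector = list(
      variance_threshold = list(
        id = "variance_threshold", role = "Selector",
        params = list(threshold = c(0, 0.01, 0.05, 0.1)),
        fit = function(M, y, params, ctx, rows) {
          v <- apply(M, 2, stats::var)
          keep <- colnames(M)[v > params$threshold]
          if (length(keep) == 0) keep <- colnames(M)[which.max(v)]
          keep
        },
        transform = function(state, M) M[, intersect(state, colnames(M)), drop = FALSE]
      ),
      select_percentile = list(
        id = "select_percentile", role = "Selector",
        params = list(percentile = c(25, 50, 75, 100)),
        fit = function(M, y, params, ctx, rows) {
          score <- abs(suppressWarnings(stats::cor(M, y)))[, 1]
          score[is.na(score)] <- 0
          n_keep <- max(1L, ceiling(ncol(M) * params$percentile / 100))
          colnames(M)[order(score, decreasing = TRUE)[seq_len(n_keep)]]
        },
        transform = function(state, M) M[, intersect(state, colnames(M)), drop = FALSE]
      )
    ),
    Transformer = list(
      standard_scaler = list(
        id = "standard_scaler", role = "Transformer", params = list(),
        fit = function(M, y, params, ctx, rows) {
          s <- apply(M, 2, stats::sd)
          list(center = colMeans(M), scale = ifelse(s > 0, s, 1))
        },
        transform = function(state, M) {
          scale(M, center = state$center[colnames(M)], scale = state$scale[colnames(M)])
        }
      ),
      minmax_scaler = list(
        id = "minmax_scaler", role = "Transformer", params = list(),
        fit = function(M, y, params, ctx, rows) {
          lo <- apply(M, 2, min)
          hi <- apply(M, 2, max)
          list(lo = lo, range = ifelse(hi > lo, hi - lo, 1))
        },
        transform = function(state, M) {
          scale(M, center = state$lo[colnames(M)], scale = state$range[colnames(M)])
        }
      ),
      polynomial_squares = list(
        id = "polynomial_squares", role = "Transformer", params = list(),
        fit = function(M, y, params, ctx, rows) colnames(M),
        transform = function(state, M) {
          sq <- M^2
          colnames(sq) <- paste0(colnames(M), "__sq")
          cbind(M, sq)
        }
      )
    ),
    Regressor = list(
      linear_reg = list(
        id = "linear_reg", role = "Regressor", params = list(),
        fit = function(M, y, params, ctx, rows) {
          list(coef = lstsq_min_norm(cbind(1, M), y), cols = colnames(M))
        },
        predict = function(state, M) {
          drop(cbind(1, M[, state$cols, drop = FALSE]) %*% state$coef)
        }
      ),
      ridge_reg = list(
        id = "ridge_reg", role = "Regressor",
        params = list(lambda = c(0.01, 0.1, 1, 10)),
        fit = function(M, y, params, ctx, rows) {
          s <- apply(M, 2, stats::sd)
          scale_ <- ifelse(s > 0, s, 1)
          Xs <- scale(M, center = colMeans(M), scale = scale_)
          b <- solve(
            crossprod(Xs) + params$lambda * diag(ncol(Xs)),
            crossprod(Xs, y - mean(y))
          )
          list(center = colMeans(M), scale = scale_, b = b, y0 = mean(y), cols = colnames(M))
        },
        predict = function(state, M) {
          Xs <- scale(M[, state$cols, drop = FALSE], center = state$center, scale = state$scale)
          drop(state$y0 + Xs %*% state$b)
        }
      ),
      tree_reg = list(
        id = "tree_reg", role = "Regressor",
        params = list(maxdepth = c(2, 3, 5)),
        fit = function(M, y, params, ctx, rows) {
          df <- safe_df(M)
          fit <- rpart::rpart(.y ~ .,
            data = cbind(df$data, .y = y), method = "anova",
            control = rpart::rpart.control(
              maxdepth = params$maxdepth, xval = 0, cp = 0.005, minsplit = 10
            )
          )
          list(fit = fit, name_map = df$map, cols = colnames(M))
        },
        predict = function(state, M) {
          unname(stats::predict(state$fit, newdata = safe_df(M, state$name_map)$data))
        }
      )
    ),
    Classifier = list(
      lda_clf = list(
        id = "lda_clf", role = "Classifier", params = list(),
        fit = function(M, y, params, ctx, rows) {
          keep <- colnames(M)[apply(M, 2, stats::sd) > 0]
          if (length(keep) == 0) abort("no non-constant predictors for LDA")
          fit <- MASS::lda(M[, keep, drop = FALSE], grouping = factor(y))
          list(fit = fit, cols = keep)
        },
        predict = function(state, M) {
          cls <- stats::predict(state$fit, M[, state$cols, drop = FALSE])$class
          as.numeric(as.character(cls))
        }
      ),
      tree_clf = list(
        id = "tree_clf", role = "Classifier",
        params = list(maxdepth = c(2, 3, 5)),
        fit = function(M, y, params, ctx, rows) {
          df <- safe_df(M)
          fit <- rpart::rpart(.y ~ .,
            data = cbind(df$data, .y = factor(y)), method = "class",
            control = rpart::rpart.control(
              maxdepth = params$maxdepth, xval = 0, cp = 0.005, minsplit = 10
            )
          )
          list(fit = fit, name_map = df$map, cols = colnames(M))
        },
        predict = function(state, M) {
          cls <- stats::predict(state$fit, newdata = safe_df(M, state$name_map)$data, type = "class")
          as.numeric(as.character(cls))
        }
      )
    )
  )
}

# rpart formulas need syntactic column names; map them reversibly
safe_df <- function(M, map = NULL) {
  if (is.null(map)) {
    map <- stats::setNames(sprintf("V%d", seq_len(ncol(M))), colnames(M))
  }
  M <- M[, names(map), drop = FALSE]
  colnames(M) <- unname(map)
  list(data = as.data.frame(M), map = map)
}

#' Default operator pool for the pipeline search
#'
#' A compact, deterministic set of operators per template role: the Feature
#' Set Selector, the residualizing transformer, variance-threshold and
#' correlation-percentile selectors, scaling and polynomial transformers,
#' linear / ridge / tree regressors and LDA / tree classifiers. The
#' `FeatureSetSelector`'s `set_name` grid is filled from `collection`.
#'
#' @param collection A [feature_set_collection()] (needed when the template
#'   contains a `FeatureSetSelector` step).
#' @return A named list: role -> list of operator definitions.
#' @export
default_operator_pool <- function(collection = NULL) {
  pool <- op_registry()
  if (!is.null(collection)) {
    pool$FeatureSetSelector$fss$params$set_name <- collection$set_name
  }
  pool
}

# --- in-pipeline feature residualization ------------------------------------

# Fit residual models for every mapped feature on `rows` of ctx$pred_data.
# Cached per row-set: the models for a given training row set do not depend
# on which features the FSS kept (per-feature fits are independent), so one
# fit per split serves every pipeline.
fit_feature_residualizers <- function(ctx, rows) {
  key <- paste(sort(rows), collapse = ",")
  cached <- ctx$res_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  map <- ctx$map
  data <- ctx$pred_data
  entries <- tibble(variable = map$variable, covariates = map$covariates)
  entries <- entries[entries$variable %in% names(data), ]
  groups <- list()
  if (nrow(entries) > 0) {
    entries$kind <- unname(ctx$kinds[entries$variable])
    cont <- entries[entries$kind == "continuous", ]
    key_cov <- vapply(cont$covariates, paste, character(1), collapse = "\r")
    for (k in unique(key_cov)) {
      grp <- cont[key_cov == k, ]
      covs <- grp$covariates[[1]]
      X <- cbind(1, as.matrix(data[rows, covs, drop = FALSE]))
      V <- as.matrix(data[rows, grp$variable, drop = FALSE])
      groups[[length(groups) + 1]] <- list(
        type = "ols", covs = covs, vars = grp$variable,
        coef = lstsq_min_norm(X, V)
      )
    }
    for (i in which(entries$kind != "continuous")) {
      var <- entries$variable[i]
      covs <- entries$covariates[[i]]
      model <- fit_residual_model(data[[var]], data[covs], rows, kind = entries$kind[i])
      groups[[length(groups) + 1]] <- list(type = "cat", covs = covs, vars = var, model = model)
    }
  }
  state <- list(groups = groups, drop = ctx$covariate_names)
  ctx$res_cache[[key]] <- state
  state
}

# Apply fitted residualizers to any matrix holding the needed columns, then
# drop covariate columns.
apply_feature_residualizers <- function(state, M) {
  for (g in state$groups) {
    vars <- intersect(g$vars, colnames(M))
    if (length(vars) == 0) next
    X <- cbind(1, M[, g$covs, drop = FALSE])
    if (g$type == "ols") {
      M[, vars] <- M[, vars, drop = FALSE] - X %*% g$coef[, vars, drop = FALSE]
    } else {
      M[, vars] <- residuals(g$model, v = M[, vars], C = M[, g$covs, drop = FALSE])
    }
  }
  M[, setdiff(colnames(M), state$drop), drop = FALSE]
}

#' Restrict a table's features to one named feature set
#'
#' The Feature Set Selector pipeline step: feature-role columns are
#' restricted to the named set's members present in the table (intersection
#' semantics — set members absent from the table are ignored); covariate,
#' indicator, residual and target columns pass through untouched.
#'
#' @param table An [adjusted_table].
#' @param collection A [feature_set_collection()].
#' @param set_name Name of the set to select.
#' @return The table with feature columns restricted to the set.
#' @export
feature_set_select <- function(table, collection, set_name) {
  members <- set_members(collection, set_name)
  feats <- feature_cols(table)
  sel <- intersect(members, feats)
  if (length(sel) == 0) {
    abort(sprintf("feature set '%s' shares no members with the table's features", set_name))
  }
  roles <- col_roles(table)
  keep <- names(roles)[roles != "feature" | names(roles) %in% sel]
  keep_columns(table, keep)
}

#' In-pipeline leakage-free feature residualization
#'
#' The residualizing transformer step, usable standalone: in `"fit"` context
#' it fits covariate models for every mapped feature on the presented rows,
#' replaces those features by their residuals, drops the covariate columns,
#' and returns the fitted models; in `"transform"` context it applies
#' previously fitted models to new rows (this is how test rows receive
#' residuals from train-fitted models).
#'
#' @param table An [adjusted_table] (rows = the presented rows).
#' @param map An [adjustment_map]; only its feature entries are used.
#' @param context `"fit"` or `"transform"`.
#' @param models Fitted models from a prior `"fit"` call (required for
#'   `"transform"`).
#' @return A list with `table` (residualized, covariates dropped) and
#'   `models`.
#' @export
resadj_transform <- function(table, map, context = c("fit", "transform"), models = NULL) {
  context <- match.arg(context)
  roles <- col_roles(table)
  kinds <- col_kinds(table)
  covs <- covariate_cols(table)
  if (context == "fit") {
    ctx <- list(
      map = map, pred_data = as_tibble(as.data.frame(table)),
      kinds = kinds, covariate_names = covs,
      res_cache = new.env(parent = emptyenv())
    )
    models <- fit_feature_residualizers(ctx, seq_len(nrow(table)))
  } else if (is.null(models)) {
    abort("transform context requires models from a prior fit")
  }
  vals <- as.matrix(as.data.frame(table)[, c(
    setdiff(names(roles)[kinds != "nominal"], character(0))
  ), drop = FALSE])
  out_m <- apply_feature_residualizers(models, vals)
  out <- dplyr::bind_cols(tibble(sample_id = table$sample_id), as_tibble(out_m))
  adjusted_vars <- unlist(lapply(models$groups, `[[`, "vars"))
  kinds[intersect(adjusted_vars, names(kinds))] <- "continuous"
  list(table = set_table_meta(out, roles, kinds), models = models)
}
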