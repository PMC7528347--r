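#' Parse and validate a pipeline template
#'
#' A template is an ordered constraint on pipeline step roles, written as a
#' hyphen-separated string, e.g.
#' `"FeatureSetSelector-resAdjTransformer-Transformer-Regressor"`. The last
#' step must be `Regressor` or `Classifier`; a `resAdjTransformer`, if
#' present, must be the first step or come immediately after a leading
#' `FeatureSetSelector` (covariate columns must be consumed before generic
#' steps see the data); a `FeatureSetSelector` can only be the first step.
#'
#' @param template Template string or character vector of roles.
#' @return Character vector of roles with class `pipeline_template`.
#' @export
pipeline_template <- function(template) {
  steps <- if (length(template) == 1) strsplit(template, "-", fixed = TRUE)[[1]] else template
  known <- c(
    "FeatureSetSelector", "resAdjTransformer", "Selector", "Transformer",
    "Regressor", "Classifier"
  )
  bad <- setdiff(steps, known)
  if (length(bad) > 0) abort(sprintf("unknown template role(s): %s", toString(bad)))
  if (!steps[length(steps)] %in% c("Regressor", "Classifier")) {
    abort("the last template step must be Regressor or Classifier")
  }
  if (sum(steps %in% c("Regressor", "Classifier")) > 1) {
    abort("only the final step may be an estimator")
  }
  fss_pos <- which(steps == "FeatureSetSelector")
  if (length(fss_pos) > 0 && !identical(fss_pos, 1L)) {
    abort("FeatureSetSelector must be the first step")
  }
  ra_pos <- which(steps == "resAdjTransformer")
  if (length(ra_pos) > 1) abort("at most one resAdjTransformer step")
  if (length(ra_pos) == 1) {
    ok <- ra_pos == 1 || (ra_pos == 2 && steps[1] == "FeatureSetSelector")
    if (!ok) {
      abort("resAdjTransformer must be the first step or immediately follow a FeatureSetSelector")
    }
  }
  structure(steps, class = "pipeline_template")
}

# --- individuals -------------------------------------------------------------

new_individual <- function(steps, created) {
  structure(
    list(steps = steps, cv_score = NA_real_, complexity = length(steps),
         holdout_score = NULL, created = created),
    class = "pipeline_individual"
  )
}

individual_signature <- function(ind) {
  paste(vapply(ind$steps, function(s) {
    pv <- if (length(s$params)) {
      paste(names(s$params), vapply(s$params, format, character(1)), sep = "=", collapse = ",")
    } else {
      ""
    }
    paste0(s$op, "(", pv, ")")
  }, character(1)), collapse = "|")
}

#' @export
format.pipeline_individual <- function(x, ...) individual_signature(x)

#' @export
print.pipeline_individual <- function(x, ...) {
  cat("# pipeline:", individual_signature(x), "\n")
  if (!is.na(x$cv_score)) cat(sprintf("#   cv_score: %.4f\n", x$cv_score))
  if (!is.null(x$holdout_score)) cat(sprintf("#   holdout_score: %.4f\n", x$holdout_score))
  invisible(x)
}

sample_step <- function(role, pool, rng_choice = sample) {
  ops <- pool[[role]]
  if (is.null(ops) || length(ops) == 0) abort(sprintf("operator pool has no operators for role %s", role))
  op <- ops[[rng_choice(length(ops), 1)]]
  params <- lapply(op$params, function(grid) {
    if (is.null(grid)) abort(sprintf("operator '%s' has an unfilled hyperparameter grid", op$id))
    grid[[rng_choice(length(grid), 1)]]
  })
  list(role = role, op = op$id, params = params)
}

random_individual <- function(template, pool, created) {
  new_individual(lapply(unclass(template), sample_step, pool = pool), created)
}

mutate_individual <- function(ind, template, pool, created) {
  steps <- ind$steps
  # only steps with something to vary (hyperparameters or alternative
  # operators) are worth mutating
  mutable <- which(vapply(steps, function(s) {
    length(s$params) > 0 || length(pool[[s$role]]) > 1
  }, logical(1)))
  if (length(mutable) == 0) {
    return(new_individual(steps, created))
  }
  i <- mutable[sample.int(length(mutable), 1)]
  role <- steps[[i]]$role
  ops <- pool[[role]]
  swap_possible <- length(ops) > 1
  has_params <- length(steps[[i]]$params) > 0
  do_swap <- swap_possible && (!has_params || stats::runif(1) < 0.5)
  if (do_swap) {
    repeat {
      cand <- sample_step(role, pool)
      if (cand$op != steps[[i]]$op || !swap_possible) break
    }
    steps[[i]] <- cand
  } else if (has_params) {
    p <- sample.int(length(steps[[i]]$params), 1)
    grid <- ops[[steps[[i]]$op]]$params[[p]]
    steps[[i]]$params[[p]] <- grid[[sample.int(length(grid), 1)]]
  }
  new_individual(steps, created)
}

crossover_individuals <- function(a, b, created) {
  L <- length(a$steps)
  if (L < 2) {
    return(new_individual(a$steps, created))
  }
  cut <- sample.int(L - 1, 1)
  new_individual(c(a$steps[seq_len(cut)], b$steps[(cut + 1):L]), created)
}

# deterministic ordering: score desc, then complexity asc, then creation asc
better_than <- function(a, b) {
  if (is.na(a$cv_score)) return(FALSE)
  if (is.na(b$cv_score)) return(TRUE)
  if (a$cv_score != b$cv_score) return(a$cv_score > b$cv_score)
  if (a$complexity != b$complexity) return(a$complexity < b$complexity)
  a$created < b$created
}

# --- pipeline fitting --------------------------------------------------------

build_search_ctx <- function(data, template, collection, pool, metric) {
  adjusted <- inherits(data, "resadj_dataset")
  tab <- if (adjusted) data$table else data
  roles <- col_roles(tab)
  kinds <- col_kinds(tab)
  covs <- covariate_cols(tab)
  use_covs <- "resAdjTransformer" %in% template
  pred_cols <- c(feature_cols(tab), if (use_covs) covs)
  # nominal columns cannot enter numeric pipelines; their encoded columns do
  pred_cols <- pred_cols[kinds[pred_cols] != "nominal"]
  map <- if (adjusted) data$map else NULL
  list(
    adjusted = adjusted, resadj = if (adjusted) data else NULL,
    table = tab, pred_data = as_tibble(as.data.frame(tab))[pred_cols],
    pred_cols = pred_cols, covariate_names = if (use_covs) covs else character(0),
    kinds = kinds, target = target_col(tab), collection = collection,
    pool = pool, metric = metric, map = map,
    res_cache = new.env(parent = emptyenv())
  )
}

ctx_target <- function(ctx, rows) {
  if (ctx$adjusted) {
    target_for_rows(ctx$resadj, rows)
  } else {
    ctx$table[[ctx$target]][rows]
  }
}

fit_pipeline_steps <- function(ind, ctx, rows) {
  y <- ctx_target(ctx, rows)
  M <- as.matrix(ctx$pred_data[rows, , drop = FALSE])
  states <- vector("list", length(ind$steps))
  for (i in seq_along(ind$steps)) {
    s <- ind$steps[[i]]
    op <- ctx$pool[[s$role]][[s$op]]
    st <- op$fit(M, y, s$params, ctx, rows)
    states[[i]] <- st
    if (!is.null(op$transform)) M <- op$transform(st, M)
  }
  list(states = states, steps = ind$steps, rows = rows)
}

predict_pipeline_steps <- function(fitted, ctx, newM) {
  M <- newM
  for (i in seq_along(fitted$steps)) {
    s <- fitted$steps[[i]]
    op <- ctx$pool[[s$role]][[s$op]]
    if (!is.null(op$transform)) {
      M <- op$transform(fitted$states[[i]], M)
    } else {
      return(op$predict(fitted$states[[i]], M))
    }
  }
  abort("pipeline has no estimator step")
}

evaluate_individual <- function(ind, ctx, plan, seed) {
  sig <- individual_signature(ind)
  withr::with_seed(str_seed(sig, seed), {
    scores <- vapply(plan$splits, function(s) {
      fitted <- fit_pipeline_steps(ind, ctx, s$train)
      preds <- predict_pipeline_steps(fitted, ctx, as.matrix(ctx$pred_data[s$test, , drop = FALSE]))
      if (ctx$adjusted) {
        residual_scorer(ctx$resadj, preds, s$test, metric = ctx$metric)
      } else {
        score_metric(ctx$metric, ctx$table[[ctx$target]][s$test], preds)
      }
    }, numeric(1))
    mean(scores)
  })
}

#' Score predictions against the correct per-split residual target
#'
#' The residual-aware scorer: given predictions for a presented row set, it
#' resolves which CV split those rows belong to via [identify_split()] and
#' scores against that split's precomputed residual-target column (or the
#' full-data residual column for the final refit).
#'
#' @param resadj A [build_resadj_dataset()] result.
#' @param predictions Numeric predictions aligned to `presented_rows`.
#' @param presented_rows Integer row indices into `resadj$table`.
#' @param metric `"r2"` or `"neg_mse"`.
#' @return A single score.
#' @export
residual_scorer <- function(resadj, predictions, presented_rows,
                            metric = c("r2", "neg_mse")) {
  metric <- match.arg(metric)
  if (length(predictions) != length(presented_rows)) {
    abort("predictions must align with presented_rows")
  }
  observed <- target_for_rows(resadj, presented_rows)
  score_metric(metric, observed, predictions)
}

# --- the GP loop -------------------------------------------------------------

#' Evolve pipelines under a template with residual-aware CV scoring
#'
#' Genetic-programming search over configured pipelines. The initial
#' population is sampled uniformly from the template's roles and the
#' operator pool's hyperparameter grids; variation uses per-step
#' hyperparameter mutation, operator-swap mutation (combined probability
#' 0.9) and one-point crossover on step configurations (probability 0.1),
#' with elitism of 1. Every individual is scored by mean CV score over the
#' shared split plan; in adjusted mode each fit resolves its target through
#' the indicator/residual columns (leakage-free), in classic mode the raw
#' target is used. Pipelines that fail to fit score `-Inf`. The reported
#' best pipeline is the highest-scoring individual ever evaluated (ties:
#' lower complexity, then earlier creation), refit on all rows at the end;
#' if the dataset carries a holdout set the holdout score is attached.
#'
#' Identical (pipeline, split) evaluations are memoized within a run; each
#' pipeline is evaluated under a seed derived from its own configuration so
#' memoization cannot alter results.
#'
#' @param data A `resadj_dataset` (adjusted mode) or an [adjusted_table]
#'   (classic mode).
#' @param template A [pipeline_template()] or template string.
#' @param collection A [feature_set_collection()] (required when the
#'   template has a FeatureSetSelector step).
#' @param pool Operator pool; defaults to [default_operator_pool()].
#' @param population,generations GP sizes.
#' @param plan Split plan (classic mode; adjusted mode uses the dataset's).
#' @param metric `"r2"`, `"neg_mse"` or `"balanced_accuracy"`; defaults to
#'   `"r2"` in adjusted mode and, in classic mode, to
#'   `"balanced_accuracy"` for binary/ordinal targets and `"r2"` otherwise.
#' @param seed Integer seed; identical seeds give identical generation logs.
#' @return An object of class `resadj_search`: list with `best` (a
#'   `pipeline_individual` with fitted state), `log` (per-generation tibble),
#'   `mode`, `metric`, `template`, `n_evaluations`, `seed`.
#' @export
evolve <- function(data, template, collection = NULL, pool = NULL,
                   population = 20, generations = 5, plan = NULL,
                   metric = NULL, seed = 1) {
  if (population < 1) abort("population must be >= 1")
  if (generations < 0) abort("generations must be >= 0")
  template <- pipeline_template(template)
  adjusted <- inherits(data, "resadj_dataset")
  if (adjusted) {
    plan <- data$plan
    metric <- metric %||% "r2"
    if (template[length(template)] != "Regressor") {
      abort("adjusted mode replaces the target by continuous residuals; the template must end in a Regressor")
    }
  } else {
    plan <- plan %||% make_split_plan(nrow(data), seed = seed)
    validate_split_plan(plan, nrow(data))
    tkind <- col_kinds(data)[[target_col(data)]]
    metric <- metric %||% if (tkind %in% c("binary", "ordinal")) "balanced_accuracy" else "r2"
  }
  if ("FeatureSetSelector" %in% template && is.null(collection)) {
    abort("template has a FeatureSetSelector step; supply a feature-set collection")
  }
  pool <- pool %||% default_operator_pool(collection)
  ctx <- build_search_ctx(data, template, collection, pool, metric)

  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_scored <- function(ind) {
    sig <- individual_signature(ind)
    hit <- memo[[sig]]
    if (is.null(hit)) {
      hit <- tryCatch(
        list(score = evaluate_individual(ind, ctx, plan, seed), error = NULL),
        error = function(e) list(score = -Inf, error = conditionMessage(e))
      )
      memo[[sig]] <- hit
      n_eval <<- n_eval + 1L
    }
    ind$cv_score <- hit$score
    ind$error <- hit$error
    ind
  }

  withr::with_seed(seed, {
    created <- 0L
    pop <- lapply(seq_len(population), function(i) {
      created <<- created + 1L
      random_individual(template, pool, created)
    })
    pop <- lapply(pop, eval_scored)
    if (all(vapply(pop, function(x) !is.finite(x$cv_score), logical(1)))) {
      msgs <- unique(unlist(lapply(pop, `[[`, "error")))
      abort(paste0(
        "all pipelines in the initial population are invalid; first errors: ",
        paste(utils::head(msgs, 3), collapse = " | ")
      ))
    }
    best <- Reduce(function(a, b) if (better_than(b, a)) b else a, pop)
    log <- gen_log_row(0L, pop)
    tournament <- function() {
      i <- sample.int(length(pop), 2, replace = TRUE)
      if (better_than(pop[[i[1]]], pop[[i[2]]])) pop[[i[1]]] else pop[[i[2]]]
    }
    for (gen in seq_len(generations)) {
      offspring <- vector("list", population)
      for (j in seq_len(population)) {
        created <- created + 1L
        r <- stats::runif(1)
        offspring[[j]] <- if (r < 0.1) {
          crossover_individuals(tournament(), tournament(), created)
        } else {
          mutate_individual(tournament(), template, pool, created)
        }
      }
      offspring <- lapply(offspring, eval_scored)
      if (all(vapply(offspring, function(x) !is.finite(x$cv_score), logical(1))) &&
          !is.finite(best$cv_score)) {
        msgs <- unique(unlist(lapply(offspring, `[[`, "error")))
        abort(paste0(
          "all pipelines in generation ", gen, " are invalid; first errors: ",
          paste(utils::head(msgs, 3), collapse = " | ")
        ))
      }
      # elitism: the incumbent best replaces the worst offspring
      worst <- which.min(vapply(offspring, function(x) {
        if (is.finite(x$cv_score)) x$cv_score else -Inf
      }, numeric(1)))
      offspring[[worst]] <- best
      pop <- offspring
      gen_best <- Reduce(function(a, b) if (better_than(b, a)) b else a, pop)
      if (better_than(gen_best, best)) best <- gen_best
      log <- dplyr::bind_rows(log, gen_log_row(gen, pop))
    }
    if (!is.finite(best$cv_score)) {
      abort(paste0("no valid pipeline found; first error: ", best$error %||% "unknown"))
    }
    # search over: final refit on the entire (non-holdout) input
    if (adjusted) ctx$resadj$lookup_log$search_end <- ctx$resadj$lookup_log$seq
    fitted <- withr::with_seed(
      str_seed(individual_signature(best), seed),
      fit_pipeline_steps(best, ctx, seq_len(nrow(ctx$table)))
    )
    result <- structure(
      list(
        best = best, fitted = fitted, log = log, mode = if (adjusted) "adjusted" else "classic",
        metric = metric, template = template, pool = pool, collection = collection,
        ctx = ctx, plan = plan, n_evaluations = n_eval, seed = seed
      ),
      class = "resadj_search"
    )
    if (adjusted && !is.null(data$holdout)) {
      result$best$holdout_score <- holdout_score(result, data)
    }
    result
  })
}

gen_log_row <- function(gen, pop) {
  scores <- vapply(pop, `[[`, numeric(1), "cv_score")
  finite <- scores[is.finite(scores)]
  tibble(
    generation = gen,
    best_score = if (length(finite)) max(finite) else NA_real_,
    mean_score = if (length(finite)) mean(finite) else NA_real_,
    n_invalid = sum(!is.finite(scores))
  )
}

#' @export
print.resadj_search <- function(x, ...) {
  cat(sprintf(
    "# resadj_search (%s mode, metric %s): %d evaluations over %d generations\n",
    x$mode, x$metric, x$n_evaluations, max(x$log$generation)
  ))
  print(x$best)
  invisible(x)
}

#' Predict with the best pipeline of a finished search
#'
#' @param object A `resadj_search`.
#' @param newdata An [adjusted_table] (or data frame) holding the predictor
#'   columns the search was run with.
#' @param ... Unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.resadj_search <- function(object, newdata, ...) {
  M <- as.matrix(as.data.frame(newdata)[, object$ctx$pred_cols, drop = FALSE])
  predict_pipeline_steps(object$fitted, object$ctx, M)
}

#' Score the best pipeline on the prepared holdout set
#'
#' The refit pipeline (trained on all non-holdout rows) transforms the
#' holdout rows — in adjusted mode the in-pipeline residualizers were fitted
#' on non-holdout rows only — and is scored against the residualized holdout
#' target.
#'
#' @param search A finished [evolve()] result.
#' @param resadj The `resadj_dataset` it was run on; must carry a holdout.
#' @param metric Score metric (defaults to the search's).
#' @return A single score.
#' @export
holdout_score <- function(search, resadj, metric = NULL) {
  if (is.null(resadj$holdout)) abort("dataset has no holdout set")
  metric <- metric %||% search$metric
  preds <- predict(search, resadj$holdout$table)
  score_metric(metric, resadj$holdout$residual_target, preds)
}
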