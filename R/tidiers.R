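#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the steps of a pipeline individual
#'
#' @param x A `pipeline_individual`.
#' @param ... Unused.
#' @return A tibble with one row per step: `step`, `role`, `operator`,
#'   `parameters` (compact string).
#' @export
tidy.pipeline_individual <- function(x, ...) {
  purrr::imap_dfr(x$steps, function(s, i) {
    tibble(
      step = i, role = s$role, operator = s$op,
      parameters = if (length(s$params)) {
        paste(names(s$params), vapply(s$params, format, character(1)),
          sep = "=", collapse = ", "
        )
      } else {
        ""
      }
    )
  })
}

#' @rdname tidy.pipeline_individual
#' @export
glance.pipeline_individual <- function(x, ...) {
  tibble(
    cv_score = x$cv_score, complexity = x$complexity,
    holdout_score = x$holdout_score %||% NA_real_
  )
}

#' Tidy / summarise a finished pipeline search
#'
#' `tidy()` returns the per-generation log; `glance()` a one-row summary of
#' the best pipeline.
#'
#' @param x A `resadj_search`.
#' @param ... Unused.
#' @export
tidy.resadj_search <- function(x, ...) x$log

#' @rdname tidy.resadj_search
#' @export
glance.resadj_search <- function(x, ...) {
  fss <- purrr::detect(x$best$steps, function(s) s$role == "FeatureSetSelector")
  tibble(
    mode = x$mode, metric = x$metric,
    cv_score = x$best$cv_score,
    holdout_score = x$best$holdout_score %||% NA_real_,
    selected_set = if (is.null(fss)) NA_character_ else fss$params$set_name,
    pipeline = individual_signature(x$best),
    n_evaluations = x$n_evaluations, seed = x$seed
  )
}

#' @rdname kmeans_sweep
#' @param x A `dunn_sweep`.
#' @param ... Unused.
#' @export
tidy.dunn_sweep <- function(x, ...) x$table

#' @rdname kmeans_sweep
#' @export
glance.dunn_sweep <- function(x, ...) {
  tibble(best_k = x$best$k, best_dunn = x$best$dunn, seed = x$best$seed)
}

# --- plots -------------------------------------------------------------------

#' Plot the per-generation score trajectory of a search
#'
#' @param object A `resadj_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resadj_search <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, c("best_score", "mean_score"),
    names_to = "series", values_to = "score"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$score,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "generation", y = sprintf("CV score (%s)", object$metric),
      colour = NULL, title = "Pipeline search trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of the top aggregated permutation importances
#'
#' @param object An `importance_summary` from [aggregate_importance()].
#' @param top_n How many columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_summary <- function(object, top_n = 20, ...) {
  df <- utils::head(dplyr::arrange(object, dplyr::desc(.data$weighted_pct)), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$weighted_pct, y = stats::reorder(.data$column, .data$weighted_pct)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "weighted mean score decrease (% of testing score)", y = NULL,
      title = "Permutation importance"
    ) +
    ggplot2::theme_minimal()
}

#' Dunn index versus number of clusters
#'
#' @param object A `dunn_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dunn_sweep <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$k, y = .data$dunn)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best$k, linetype = "dashed") +
    ggplot2::labs(x = "k", y = "Dunn index", title = "k-means sweep") +
    ggplot2::theme_minimal()
}

#' Feature-set selection frequencies across runs
#'
#' One bar per feature set selected by at least one run, its height the
#' selection frequency; holdout scores overplotted as points.
#'
#' @param object A `recovery_result` from [recover_feature_sets()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_result <- function(object, ...) {
  freq <- selection_frequencies(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$selected_set, y = .data$holdout_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_text(
      data = freq,
      ggplot2::aes(x = .data$selected_set, y = Inf, label = sprintf("%d%%", round(100 * .data$frequency))),
      vjust = 1.5, inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "selected feature set", y = "holdout score",
      title = sprintf("Feature-set recovery (%s mode)", attr(object, "mode"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
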