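#' Permutation importance of features and covariates on the holdout set
#'
#' For each input column of a fitted pipeline (features and, in adjusted
#' mode, the covariate columns — permuting a covariate perturbs the
#' in-pipeline residualization it feeds), the column is shuffled across the
#' holdout rows `n_repeats` times with a seeded generator and the pipeline
#' re-scored; the importance is `base_score - mean(permuted scores)`.
#' Columns the pipeline never uses (e.g. dropped by the Feature Set
#' Selector) yield a decrease of exactly 0, as do zero-variance columns.
#' Negative decreases are retained, not clipped.
#'
#' @param search A finished [evolve()] result (adjusted mode).
#' @param resadj The `resadj_dataset` with a holdout set; or, for classic
#'   mode, pass `newdata` and `truth` instead.
#' @param newdata,truth Classic mode: a holdout [adjusted_table] and the
#'   observed target values.
#' @param n_repeats Number of shuffles per column (default 10).
#' @param seed Integer seed.
#' @param run_id Identifier stored on the record.
#' @return A tibble of class `importance_record` with columns `column`,
#'   `decrease`, and attributes `run_id`, `testing_score`, `n_repeats`,
#'   `seed`.
#' @export
permutation_importance <- function(search, resadj = NULL, newdata = NULL,
                                   truth = NULL, n_repeats = 10, seed = 1,
                                   run_id = 1L) {
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  if (!is.null(resadj)) {
    if (is.null(resadj$holdout)) abort("dataset has no holdout set")
    hold <- as.data.frame(resadj$holdout$table)
    observed <- resadj$holdout$residual_target
  } else {
    if (is.null(newdata) || is.null(truth)) {
      abort("supply either a resadj dataset with holdout, or newdata + truth")
    }
    hold <- as.data.frame(newdata)
    observed <- truth
  }
  cols <- search$ctx$pred_cols
  M0 <- as.matrix(hold[, cols, drop = FALSE])
  score_of <- function(M) {
    score_metric(search$metric, observed, predict_pipeline_steps(search$fitted, search$ctx, M))
  }
  base <- score_of(M0)
  m <- nrow(M0)
  decreases <- withr::with_seed(seed, {
    vapply(cols, function(col) {
      perm_scores <- vapply(seq_len(n_repeats), function(r) {
        M <- M0
        M[, col] <- M[sample.int(m), col]
        score_of(M)
      }, numeric(1))
      base - mean(perm_scores)
    }, numeric(1))
  })
  structure(
    tibble(column = cols, decrease = unname(decreases)),
    run_id = run_id, testing_score = base, n_repeats = n_repeats, seed = seed,
    class = c("importance_record", class(tibble()))
  )
}

#' Aggregate permutation importances across independent runs
#'
#' Each run's decreases are expressed as a percentage of that run's testing
#' score (`100 * decrease / score`), then averaged across runs weighted by
#' the testing score. Runs with testing score <= 0 are excluded (their
#' percentages are unstable or sign-flipped) and counted in the
#' `n_runs_excluded` attribute; a column absent from one run's record is
#' treated as decrease 0 in that run. The result is invariant under uniform
#' rescaling of all weights.
#'
#' @param records A list of `importance_record`s, or a long tibble with
#'   columns `run_id`, `testing_score`, `column`, `decrease`.
#' @return A tibble with columns `column`, `weighted_pct`,
#'   `n_runs_included`, sorted by decreasing importance; attribute
#'   `n_runs_excluded`. Class `importance_summary`.
#' @examples
#' recs <- tibble::tibble(
#'   run_id = c(1, 1, 2, 2), testing_score = c(0.5, 0.5, 1, 1),
#'   column = c("a", "b", "a", "b"), decrease = c(0.05, 0.0, 0.4, 0.1)
#' )
#' aggregate_importance(recs) # column "a": (0.5*10 + 1*40) / 1.5 = 30
#' @export
aggregate_importance <- function(records) {
  long <- if (is.data.frame(records)) {
    as_tibble(records)
  } else {
    purrr::map_dfr(records, function(r) {
      tibble(
        run_id = attr(r, "run_id"), testing_score = attr(r, "testing_score"),
        column = r$column, decrease = r$decrease
      )
    })
  }
  stopifnot(all(c("run_id", "testing_score", "column", "decrease") %in% names(long)))
  runs <- dplyr::distinct(long, .data$run_id, .data$testing_score)
  excluded <- runs$run_id[runs$testing_score <= 0]
  included <- runs[!(runs$run_id %in% excluded), ]
  if (nrow(included) == 0) abort("all runs have testing score <= 0; nothing to aggregate")
  long <- long[long$run_id %in% included$run_id, ]
  # absent columns count as decrease 0 in that run
  full <- tidyr::complete(
    long, tidyr::nesting(run_id, testing_score), column,
    fill = list(decrease = 0)
  )
  out <- full |>
    dplyr::mutate(pct = 100 * .data$decrease / .data$testing_score) |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(
      weighted_pct = sum(.data$testing_score * .data$pct) / sum(.data$testing_score),
      n_runs_included = dplyr::n()
    ) |>
    dplyr::arrange(dplyr::desc(.data$weighted_pct))
  structure(out,
    n_runs_excluded = length(excluded),
    class = c("importance_summary", class(tibble()))
  )
}
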