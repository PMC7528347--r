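#' Materialize predefined CV splits and leakage-free target residuals
#'
#' The pre-processing step for target (and target + feature) adjustment
#' workflows. For each split of the plan it appends two columns to the
#' table: an indicator column (`__split{i}_indicator`: 1 = train, 0 = test,
#' -1 = row not in the split) and a residual column
#' (`__split{i}_residual`) holding the target residualized with a covariate
#' model fitted *on that split's training rows only*. One extra column,
#' `__full_residual`, holds residuals from a model fitted on all
#' (non-holdout) rows; it is used only for the final refit/reported score
#' after the search has ended. Optionally a holdout fraction is removed
#' first: holdout rows appear in no split and influence no fitted model, and
#' their residualized target (from the full non-holdout fit) is stored
#' alongside.
#'
#' Feature adjustments are *not* applied here; they happen inside each
#' pipeline (the in-pipeline residualizing transformer), so that selectors
#' upstream of the estimator also see leakage-free features per split.
#'
#' @param table An [adjusted_table] with one target column of kind
#'   continuous, binary or ordinal.
#' @param map An [adjustment_map] with `adjust_target = TRUE`.
#' @param plan A [make_split_plan()] plan over the non-holdout rows, or
#'   `NULL` to build the default plan (5 shuffle splits, 75% train) from
#'   `seed`.
#' @param holdout_fraction Proportion of rows to reserve as holdout, or
#'   `NULL` for none.
#' @param seed Integer seed controlling the holdout draw (and the default
#'   plan).
#' @param ridge Ridge penalty for categorical target models.
#' @return An object of class `resadj_dataset`: list with elements `table`
#'   (augmented table over non-holdout rows), `plan`, `map`, `target`
#'   (target column name), `holdout` (`NULL` or
#'   `list(rows, table, residual_target)`), and `lookup_log` (environment
#'   instrumenting [identify_split()] calls).
#' @export
build_resadj_dataset <- function(table, map, plan = NULL, holdout_fraction = NULL,
                                 seed = 1, ridge = 1e-4) {
  if (!adjusts_target(map)) {
    abort(paste(
      "the adjustment map declares no target covariates;",
      "for feature-only adjustment run the search directly with a",
      "resAdjTransformer template (no pre-processing needed)"
    ))
  }
  validate_adjustment_map(map, table)
  tc <- target_col(table)
  kinds <- col_kinds(table)
  if (!kinds[[tc]] %in% c("continuous", "binary", "ordinal")) {
    abort(sprintf("target kind '%s' cannot be residualized (encode it first)", kinds[[tc]]))
  }
  m <- nrow(table)
  holdout_rows <- integer(0)
  if (!is.null(holdout_fraction) && holdout_fraction > 0) {
    if (holdout_fraction >= 1) abort("holdout_fraction must be < 1")
    n_hold <- round(holdout_fraction * m)
    holdout_rows <- withr::with_seed(seed, sort(sample.int(m, n_hold)))
  }
  keep_rows <- setdiff(seq_len(m), holdout_rows)
  tab0 <- set_table_meta(as_tibble(as.data.frame(table))[keep_rows, ], col_roles(table), kinds)
  m0 <- nrow(tab0)
  if (is.null(plan)) {
    plan <- make_split_plan(m0, n_splits = 5, scheme = "shuffle",
                            train_fraction = 0.75, seed = seed)
  }
  validate_split_plan(plan, m0)

  tcov <- target_covariates(map)
  y <- tab0[[tc]]
  C <- tab0[tcov]
  tkind <- kinds[[tc]]
  out <- as_tibble(as.data.frame(tab0))
  roles <- col_roles(tab0)
  kinds0 <- col_kinds(tab0)
  for (i in seq_along(plan$splits)) {
    s <- plan$splits[[i]]
    rows_all <- sort(union(s$train, s$test))
    ind <- rep(-1L, m0)
    ind[s$train] <- 1L
    ind[s$test] <- 0L
    model <- fit_residual_model(y, C, s$train, kind = tkind, ridge = ridge)
    res <- rep(NA_real_, m0)
    res[rows_all] <- residuals(model, v = y, C = C, rows = rows_all)
    ind_name <- sprintf("__split%d_indicator", i)
    res_name <- sprintf("__split%d_residual", i)
    out[[ind_name]] <- ind
    out[[res_name]] <- res
    roles[c(ind_name, res_name)] <- c("indicator", "residual_target")
    kinds0[c(ind_name, res_name)] <- c("ordinal", "continuous")
  }
  full_model <- fit_residual_model(y, C, seq_len(m0), kind = tkind, ridge = ridge)
  out[["__full_residual"]] <- residuals(full_model, v = y, C = C, rows = seq_len(m0))
  roles["__full_residual"] <- "residual_target"
  kinds0["__full_residual"] <- "continuous"

  holdout <- NULL
  if (length(holdout_rows) > 0) {
    htab <- set_table_meta(as_tibble(as.data.frame(table))[holdout_rows, ],
                           col_roles(table), col_kinds(table))
    holdout <- list(
      rows = holdout_rows,
      table = htab,
      residual_target = residuals(full_model,
        v = htab[[tc]], C = htab[tcov], rows = seq_len(nrow(htab))
      )
    )
  }
  structure(
    list(
      table = set_table_meta(out, roles, kinds0),
      plan = plan, map = map, target = tc, target_kind = tkind,
      holdout = holdout, seed = seed,
      lookup_log = new_lookup_log()
    ),
    class = "resadj_dataset"
  )
}

new_lookup_log <- function() {
  env <- new.env(parent = emptyenv())
  env$calls <- list()
  env$seq <- 0L
  env$search_end <- Inf
  env
}

#' @export
print.resadj_dataset <- function(x, ...) {
  cat(sprintf(
    "# resadj_dataset: %d rows, %d splits (%s), target '%s'%s\n",
    nrow(x$table), length(x$plan$splits), x$plan$scheme, x$target,
    if (is.null(x$holdout)) "" else sprintf(", %d holdout rows", length(x$holdout$rows))
  ))
  invisible(x)
}

#' Identify which CV split a presented row set belongs to
#'
#' Downstream components inside the search see only a subset of rows; by
#' matching that subset against the plan they recover which split (and hence
#' which precomputed residual column) applies. Matching is by exact row-set
#' equality: a fitting context matches a split's train set, a scoring
#' context its test set, and the full non-holdout row set maps to `"FULL"`
#' (the final refit / reported score). Anything else — zero or multiple
#' matches — is an ambiguity error signalling a CV plan mismatch, because
#' silently picking a wrong target would be far worse.
#'
#' Every call is appended to the dataset's `lookup_log`, which tests use to
#' assert that the full-data residual column is never consulted before the
#' search ends.
#'
#' @param resadj A `resadj_dataset`.
#' @param presented_rows Integer row indices (into `resadj$table`).
#' @return A list with `split` (integer index or `"FULL"`) and `context`
#'   (`"fitting"`, `"scoring"` or `"full"`).
#' @export
identify_split <- function(resadj, presented_rows) {
  if (length(presented_rows) == 0) abort("presented row set is empty")
  rows <- sort(unique(presented_rows))
  m0 <- nrow(resadj$table)
  log_call <- function(result, context) {
    lg <- resadj$lookup_log
    lg$seq <- lg$seq + 1L
    lg$calls[[lg$seq]] <- list(seq = lg$seq, split = result, context = context)
  }
  if (length(rows) == m0 && identical(rows, seq_len(m0))) {
    log_call("FULL", "full")
    return(list(split = "FULL", context = "full"))
  }
  hits <- list()
  for (i in seq_along(resadj$plan$splits)) {
    s <- resadj$plan$splits[[i]]
    if (identical(rows, sort(s$train))) hits[[length(hits) + 1]] <- list(split = i, context = "fitting")
    if (identical(rows, sort(s$test))) hits[[length(hits) + 1]] <- list(split = i, context = "scoring")
  }
  if (length(hits) != 1) {
    abort(sprintf(
      "presented rows match %d split train/test sets; cannot identify the CV split (plan mismatch?)",
      length(hits)
    ))
  }
  log_call(hits[[1]]$split, hits[[1]]$context)
  hits[[1]]
}

# Residual-target values for a presented row set, resolved via identify_split.
target_for_rows <- function(resadj, rows) {
  id <- identify_split(resadj, rows)
  col <- if (identical(id$split, "FULL")) {
    "__full_residual"
  } else {
    sprintf("__split%d_residual", id$split)
  }
  resadj$table[[col]][rows]
}
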