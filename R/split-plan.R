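#' Predefined cross-validation split plans
#'
#' The pipeline search and the target pre-processor share one fixed plan of
#' train/test row partitions, so that residual columns computed up front line
#' up exactly with the splits the search presents to its estimators. Plans
#' are fully reproducible from their seed and serializable to a sidecar CSV
#' so that independent runs (e.g. adjusted vs. classic on the same data) can
#' share identical splits.
#'
#' Two schemes are provided: `shuffle` draws independent train/test
#' partitions at `train_fraction` (default 0.75 train), and `kfold`
#' partitions the rows into `n_splits` folds whose test sets are disjoint.
#'
#' @param m Number of rows (samples) to split.
#' @param n_splits Number of splits (>= 2).
#' @param scheme `"shuffle"` or `"kfold"`.
#' @param train_fraction Training proportion per split (shuffle scheme only).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return An object of class `split_plan`: a list with elements `splits`
#'   (list of `list(train, test)` integer vectors), `scheme`,
#'   `train_fraction`, `seed`, `m`.
#' @examples
#' plan <- make_split_plan(12, n_splits = 3, seed = 1)
#' lengths(plan$splits[[1]])
#' @export
make_split_plan <- function(m, n_splits = 5, scheme = c("shuffle", "kfold"),
                            train_fraction = 0.75, seed = 1) {
  scheme <- match.arg(scheme)
  if (n_splits < 2) abort("n_splits must be >= 2")
  if (n_splits > m) abort(sprintf("n_splits (%d) exceeds sample count (%d)", n_splits, m))
  splits <- withr::with_seed(seed, {
    if (scheme == "shuffle") {
      if (train_fraction <= 0 || train_fraction >= 1) {
        abort("train_fraction must be strictly between 0 and 1")
      }
      n_train <- round(train_fraction * m)
      if (n_train < 1 || n_train >= m) abort("train_fraction leaves an empty train or test set")
      lapply(seq_len(n_splits), function(i) {
        train <- sort(sample.int(m, n_train))
        list(train = train, test = setdiff(seq_len(m), train))
      })
    } else {
      fold_of <- sample(rep_len(seq_len(n_splits), m))
      lapply(seq_len(n_splits), function(i) {
        test <- which(fold_of == i)
        list(train = setdiff(seq_len(m), test), test = test)
      })
    }
  })
  structure(
    list(
      splits = splits, scheme = scheme,
      train_fraction = if (scheme == "shuffle") train_fraction else NA_real_,
      seed = seed, m = m
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "# split_plan: %d %s splits of %d rows (seed %s)\n",
    length(x$splits), x$scheme, x$m, format(x$seed)
  ))
  invisible(x)
}

#' @describeIn make_split_plan Long-format view: one row per (split, row).
#' @param x A `split_plan`.
#' @param ... Unused.
#' @export
tidy.split_plan <- function(x, ...) {
  purrr::imap_dfr(x$splits, function(s, i) {
    tibble(
      split = i, row = c(s$train, s$test),
      is_train = rep(c(1L, 0L), c(length(s$train), length(s$test)))
    )
  })
}

#' Serialize / restore a split plan
#'
#' The sidecar CSV holds one row per (split, row) with the train/test flag,
#' plus the plan's scheme, train fraction and seed as constant columns, so a
#' restored plan is identical to the original.
#'
#' @param plan A `split_plan`.
#' @param path CSV path.
#' @return `write_split_plan()` returns `path` invisibly;
#'   `read_split_plan()` returns a `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  long <- tidy(plan)
  long$scheme <- plan$scheme
  long$train_fraction <- plan$train_fraction
  long$seed <- plan$seed
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  splits <- lapply(sort(unique(long$split)), function(i) {
    rows <- long[long$split == i, ]
    list(
      train = sort(rows$row[rows$is_train == 1L]),
      test = sort(rows$row[rows$is_train == 0L])
    )
  })
  structure(
    list(
      splits = splits, scheme = long$scheme[1],
      train_fraction = long$train_fraction[1], seed = long$seed[1],
      m = max(long$row)
    ),
    class = "split_plan"
  )
}

validate_split_plan <- function(plan, m) {
  if (plan$m > m) abort(sprintf("split plan covers %d rows but table has %d", plan$m, m))
  for (i in seq_along(plan$splits)) {
    s <- plan$splits[[i]]
    if (length(s$train) == 0 || length(s$test) == 0) {
      abort(sprintf("split %d has an empty train or test set", i))
    }
    if (length(intersect(s$train, s$test)) > 0) {
      abort(sprintf("split %d has overlapping train and test sets", i))
    }
    if (max(c(s$train, s$test)) > m) {
      abort(sprintf("split %d references rows beyond the table", i))
    }
  }
  invisible(plan)
}
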