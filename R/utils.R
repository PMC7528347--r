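#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Deterministic scalar hash of a character string, always < 2^31.
# Used to derive per-object RNG seeds from a base seed.
str_seed <- function(x, base = 0L) {
  v <- utf8ToInt(paste(x, collapse = "\r"))
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(base)) %% 2147483647)
}

# Minimum-norm least-squares solve via SVD; handles rank deficiency.
# X: m x p design (no intercept column added here), Y: m x q response matrix.
lstsq_min_norm <- function(X, Y) {
  Y <- as.matrix(Y)
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  if (!any(pos)) {
    return(matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y))))
  }
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos])
  dimnames(coef) <- list(colnames(X), colnames(Y))
  coef
}

# row-wise softmax of a linear predictor matrix (m x K), numerically stable
softmax_rows <- function(eta) {
  eta <- eta - apply(eta, 1L, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

r_squared <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  ss_res <- sum((observed - predicted)^2)
  if (ss_tot == 0) {
    return(if (ss_res == 0) 1 else -Inf)
  }
  1 - ss_res / ss_tot
}

neg_mse <- function(observed, predicted) {
  -mean((observed - predicted)^2)
}

#' Balanced accuracy of a multiclass prediction
#'
#' The unweighted mean of per-class recall over the classes observed in
#' `truth`. Used to score classifier pipelines in classic (unadjusted) mode,
#' where the target keeps its original multiclass coding.
#'
#' @param truth Vector of observed class labels.
#' @param predicted Vector of predicted class labels, same length.
#' @return A single number in \[0, 1\].
#' @examples
#' balanced_accuracy(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 2, 3, 1))
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  classes <- unique(truth)
  recalls <- vapply(classes, function(k) {
    mean(predicted[truth == k] == k)
  }, numeric(1))
  mean(recalls)
}

score_metric <- function(metric, observed, predicted) {
  switch(metric,
    r2 = r_squared(observed, predicted),
    neg_mse = neg_mse(observed, predicted),
    balanced_accuracy = balanced_accuracy(observed, predicted),
    abort(sprintf("unknown metric '%s'", metric))
  )
}
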