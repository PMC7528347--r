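#' Dunn index of a clustering
#'
#' The ratio of the minimum intercluster distance (smallest pairwise
#' Euclidean distance between members of different clusters) to the maximum
#' intracluster diameter (largest pairwise distance within any cluster).
#' Higher values mean better-separated, more compact clusters. Degenerate
#' conventions: when every cluster has zero diameter but clusters are
#' separated the index is `+Inf` (reported with a warning — e.g. all
#' singletons); when both numerator and denominator are zero it is defined
#' as 0 (no evidence of separation).
#'
#' @param points Numeric matrix or data frame, samples in rows.
#' @param labels Cluster assignment, one per row; at least 2 nonempty
#'   clusters.
#' @return A nonnegative number (possibly `Inf`).
#' @examples
#' pts <- matrix(c(0, 1, 10, 11), ncol = 1)
#' dunn_index(pts, c("A", "A", "B", "B")) # 9 / 1
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels))
  clusters <- unique(labels)
  if (length(clusters) < 2) abort("Dunn index needs at least 2 clusters")
  D <- as.matrix(stats::dist(points))
  same <- outer(labels, labels, `==`)
  diag(same) <- NA
  inter <- D[!is.na(same) & !same]
  intra <- D[!is.na(same) & same]
  min_inter <- min(inter)
  max_intra <- if (length(intra) == 0) 0 else max(intra)
  if (max_intra == 0) {
    if (min_inter == 0) {
      return(0)
    }
    warn("all intracluster diameters are zero; Dunn index is +Inf")
    return(Inf)
  }
  min_inter / max_intra
}

#' Sweep k-means over k and select k by the Dunn index
#'
#' For each `k` in `k_min:k_max`, runs seeded k-means with `n_init` random
#' restarts (keeping the solution with the lowest within-cluster sum of
#' squares), computes the Dunn index, and returns the clustering whose Dunn
#' index is largest (ties broken toward smaller `k`). This is the
#' covariate-relevance diagnostic used before deciding what to adjust for:
#' cluster the samples, then ask (via [bhi()]) how homogeneous the clusters
#' are with respect to each candidate covariate.
#'
#' @param points Numeric matrix or data frame, samples in rows.
#' @param k_min,k_max Range of cluster counts (`k_min >= 2`,
#'   `k_max <= nrow - 1`).
#' @param seed Integer seed; the sweep is deterministic given the seed.
#' @param n_init Random restarts per `k`.
#' @return An object of class `dunn_sweep`: list with `best`
#'   (`list(k, labels, dunn, seed)`) and `table` (per-k tibble with `k`,
#'   `dunn`, `tot_withinss`).
#' @export
kmeans_sweep <- function(points, k_min = 2, k_max = 10, seed = 1, n_init = 10) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (k_min < 2) abort("k_min must be >= 2")
  if (k_max > m - 1) abort("k_max must be <= number of samples - 1")
  if (k_min > k_max) abort("k_min must be <= k_max")
  rows <- purrr::map(k_min:k_max, function(k) {
    km <- withr::with_seed(seed + k, kmeans_robust(points, k, n_init))
    list(k = k, labels = km$cluster, dunn = dunn_index(points, km$cluster),
         tot_withinss = km$tot.withinss)
  })
  table <- purrr::map_dfr(rows, function(r) {
    tibble(k = r$k, dunn = r$dunn, tot_withinss = r$tot_withinss)
  })
  best_i <- which.max(table$dunn) # ties -> first, i.e. smaller k
  best <- rows[[best_i]]
  structure(
    list(best = list(k = best$k, labels = best$labels, dunn = best$dunn, seed = seed),
         table = table),
    class = "dunn_sweep"
  )
}

# stats::kmeans can abort on an empty-cluster configuration for unlucky
# starts; retry with shifted seeds rather than failing the sweep.
kmeans_robust <- function(points, k, n_init, max_tries = 5) {
  for (try in seq_len(max_tries)) {
    km <- tryCatch(
      stats::kmeans(points, centers = k, nstart = n_init, iter.max = 100),
      error = function(e) NULL
    )
    if (!is.null(km)) {
      return(km)
    }
    # reshuffle the RNG position so the next attempt draws new centers
    stats::runif(try)
  }
  abort(sprintf("k-means failed for k = %d after %d attempts", k, max_tries))
}

#' @export
print.dunn_sweep <- function(x, ...) {
  cat(sprintf(
    "# dunn_sweep: best k = %d (Dunn %.4f) over k in %d..%d\n",
    x$best$k, x$best$dunn, min(x$table$k), max(x$table$k)
  ))
  invisible(x)
}

#' Biological Homogeneity Index of a clustering
#'
#' For every cluster with at least 2 members, the proportion of unordered
#' member pairs sharing the same annotation; the BHI is the unweighted mean
#' of these proportions over qualifying clusters (each qualifying cluster
#' contributes equally; set `weight = "pairs"` to pool all pairs instead).
#' Clusters with fewer than 2 members are skipped. Values lie in \[0, 1\]:
#' 1 means every cluster is annotation-pure, values near 0 mean the
#' annotation is unrelated to the clustering — hence a covariate with high
#' BHI is one the clustering (and so the features) is structured by, and a
#' strong candidate for adjustment.
#'
#' @param labels Cluster assignment per sample.
#' @param annotations Category annotation per sample (e.g. compound, dose).
#' @param weight `"cluster"` (unweighted mean over clusters, default) or
#'   `"pairs"` (pooled over all within-cluster pairs).
#' @return A number in \[0, 1\].
#' @examples
#' bhi(c(1, 1, 1, 2, 2, 2), c("A", "A", "B", "C", "C", "C")) # (1/3 + 1) / 2
#' @export
bhi <- function(labels, annotations, weight = c("cluster", "pairs")) {
  weight <- match.arg(weight)
  stopifnot(length(labels) == length(annotations))
  labels <- as.character(labels)
  annotations <- as.character(annotations)
  per_cluster <- lapply(split(annotations, labels), function(ann) {
    n <- length(ann)
    if (n < 2) {
      return(NULL)
    }
    counts <- table(ann)
    same_pairs <- sum(choose(counts, 2))
    c(prop = same_pairs / choose(n, 2), pairs = choose(n, 2), same = same_pairs)
  })
  per_cluster <- per_cluster[!vapply(per_cluster, is.null, logical(1))]
  if (length(per_cluster) == 0) abort("no cluster has 2 or more members")
  if (weight == "cluster") {
    mean(vapply(per_cluster, `[[`, numeric(1), "prop"))
  } else {
    sum(vapply(per_cluster, `[[`, numeric(1), "same")) /
      sum(vapply(per_cluster, `[[`, numeric(1), "pairs"))
  }
}

#' Covariate-relevance diagnostic: BHI of the Dunn-optimal clustering
#'
#' Convenience wrapper: sweep k-means by Dunn index over the feature
#' columns, then compute the BHI of the selected clustering against each
#' supplied annotation column.
#'
#' @param table An [adjusted_table].
#' @param annotations A data frame of per-sample category columns (or a
#'   named list of vectors).
#' @param k_min,k_max,seed,n_init Passed to [kmeans_sweep()].
#' @return A list with `sweep` (the `dunn_sweep`) and `bhi` (tibble:
#'   `annotation`, `bhi`).
#' @export
diagnose_covariates <- function(table, annotations, k_min = 2, k_max = 10,
                                seed = 1, n_init = 10) {
  pts <- as.matrix(as.data.frame(table)[, feature_cols(table), drop = FALSE])
  sweep <- kmeans_sweep(pts, k_min, k_max, seed = seed, n_init = n_init)
  annotations <- as.data.frame(annotations)
  scores <- tibble(
    annotation = names(annotations),
    bhi = vapply(annotations, function(a) bhi(sweep$best$labels, a), numeric(1))
  )
  list(sweep = sweep, bhi = scores)
}
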