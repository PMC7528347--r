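#' Declare which variables are residualized on which covariates
#'
#' An adjustment map lists, per adjusted variable, the covariate columns to
#' regress out of it, and optionally a set of covariates to regress out of
#' the target. The on-disk format is a two-column delimited file
#' (`variable`, `covariates`), the second field a comma-separated covariate
#' list; the reserved variable name `TARGET` declares the target adjustment.
#' An empty file yields an empty map with `adjust_target = FALSE`
#' (classic, unadjusted mode).
#'
#' @param entries A named list mapping adjusted feature column names to
#'   character vectors of covariate column names (may be empty).
#' @param target_covariates Covariates to adjust the target by, or `NULL`.
#' @return A tibble of class `adjustment_map` with columns `variable` and
#'   `covariates` (list), and attributes `adjust_target`, `target_covariates`.
#' @examples
#' adjustment_map(list(g1 = c("batch", "dose")), target_covariates = "batch")
#' @export
adjustment_map <- function(entries = list(), target_covariates = NULL) {
  entries <- entries %||% list()
  map <- tibble(
    variable = names(entries) %||% character(0),
    covariates = lapply(unname(entries), as.character)
  )
  structure(map,
    adjust_target = length(target_covariates) > 0,
    target_covariates = as.character(target_covariates %||% character(0)),
    class = c("adjustment_map", class(tibble()))
  )
}

#' @rdname adjustment_map
#' @param map An `adjustment_map`.
#' @export
adjusts_target <- function(map) isTRUE(attr(map, "adjust_target", exact = TRUE))

#' @rdname adjustment_map
#' @export
target_covariates <- function(map) attr(map, "target_covariates", exact = TRUE)

#' @rdname adjustment_map
#' @param path Path to the adjustment-map file.
#' @param table An [adjusted_table] to validate the map against.
#' @export
read_adjustment_map <- function(path, table = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^variable\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    map <- adjustment_map()
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    # variable is the first field; the rest of the line is the covariate list
    first_sep <- regexpr(sep, lines, fixed = TRUE)
    if (any(first_sep < 0)) {
      abort(sprintf("adjustment-map line %d has no covariate field", which(first_sep < 0)[1]))
    }
    vars <- trimws(substr(lines, 1, first_sep - 1))
    covs <- substr(lines, first_sep + 1, nchar(lines))
    covs <- lapply(strsplit(gsub("\"", "", covs), ","), function(v) trimws(v[nzchar(trimws(v))]))
    is_target <- vars == "TARGET"
    if (sum(is_target) > 1) abort("multiple TARGET rows in adjustment map")
    map <- adjustment_map(
      entries = stats::setNames(covs[!is_target], vars[!is_target]),
      target_covariates = if (any(is_target)) covs[is_target][[1]] else NULL
    )
  }
  if (!is.null(table)) validate_adjustment_map(map, table)
  map
}

#' @rdname adjustment_map
#' @export
write_adjustment_map <- function(map, path) {
  rows <- purrr::map2_chr(map$variable, map$covariates, function(v, c) {
    sprintf("%s,\"%s\"", v, paste(c, collapse = ","))
  })
  if (adjusts_target(map)) {
    rows <- c(rows, sprintf("TARGET,\"%s\"", paste(target_covariates(map), collapse = ",")))
  }
  writeLines(c("variable,covariates", rows), path)
  invisible(path)
}

#' @rdname adjustment_map
#' @export
validate_adjustment_map <- function(map, table) {
  roles <- col_roles(table)
  all_covs <- unique(c(unlist(map$covariates), target_covariates(map)))
  unknown <- setdiff(c(map$variable, all_covs), names(roles))
  if (length(unknown) > 0) {
    abort(sprintf("adjustment map references unknown column(s): %s", toString(unknown)))
  }
  self_adj <- map$variable[purrr::map2_lgl(map$variable, map$covariates, `%in%`)]
  if (length(self_adj) > 0) {
    abort(sprintf("column(s) listed as their own covariate: %s", toString(self_adj)))
  }
  bad_adjusted <- intersect(map$variable, all_covs)
  if (length(bad_adjusted) > 0) {
    abort(sprintf(
      "column(s) listed both as adjusted and as covariate: %s", toString(bad_adjusted)
    ))
  }
  not_cov <- all_covs[roles[all_covs] != "covariate"]
  if (length(not_cov) > 0) {
    abort(sprintf("covariate(s) in map lack role 'covariate': %s", toString(not_cov)))
  }
  invisible(map)
}
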