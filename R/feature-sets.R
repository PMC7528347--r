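#' Named collections of feature IDs (GMT format)
#'
#' Feature sets group feature columns into named, possibly overlapping sets
#' (typically pathways), from which the pipeline search's Feature Set
#' Selector step picks one set per pipeline. Stored as a tibble with one row
#' per set and a list-column of member IDs.
#'
#' `read_feature_sets()` parses the GMT dialect: one set per line, tab
#' separated, fields `name`, `description`, then one or more member IDs.
#' Members absent from a particular table are tolerated at parse time and
#' intersected away at selection time.
#'
#' @param sets A named list of character vectors (members), or a tibble with
#'   columns `set_name`, `description`, `members`.
#' @param descriptions Optional character vector of descriptions, recycled.
#' @return A tibble of class `feature_set_collection` with columns
#'   `set_name`, `description`, `members` (list of character).
#' @examples
#' fs <- feature_set_collection(list(pathA = c("g1", "g2"), pathB = c("g2", "g3", "g4")))
#' fs
#' @export
feature_set_collection <- function(sets, descriptions = "") {
  if (is.data.frame(sets)) {
    out <- as_tibble(sets[, c("set_name", "description", "members")])
  } else {
    out <- tibble(
      set_name = names(sets),
      description = rep_len(descriptions, length(sets)),
      members = lapply(unname(sets), as.character)
    )
  }
  dup <- out$set_name[duplicated(out$set_name)]
  if (length(dup) > 0) abort(sprintf("duplicate feature-set name(s): %s", toString(unique(dup))))
  empty <- out$set_name[lengths(out$members) == 0]
  if (length(empty) > 0) abort(sprintf("feature set(s) with no members: %s", toString(empty)))
  class(out) <- c("feature_set_collection", class(tibble()))
  out
}

#' @rdname feature_set_collection
#' @param path Path to a GMT file.
#' @export
read_feature_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("no feature sets in %s", path))
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parsed, function(f) sum(nzchar(f)) < 3, logical(1)))
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 non-empty fields", short[1]))
  }
  feature_set_collection(
    tibble(
      set_name = vapply(parsed, `[[`, character(1), 1L),
      description = vapply(parsed, `[[`, character(1), 2L),
      members = lapply(parsed, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
    )
  )
}

#' @rdname feature_set_collection
#' @param x A `feature_set_collection`.
#' @export
write_feature_sets <- function(x, path) {
  lines <- purrr::pmap_chr(
    list(x$set_name, x$description, x$members),
    function(n, d, m) paste(c(n, d, m), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname feature_set_collection
#' @param set_name Name of one set.
#' @export
set_members <- function(x, set_name) {
  i <- match(set_name, x$set_name)
  if (is.na(i)) abort(sprintf("unknown feature set '%s'", set_name))
  x$members[[i]]
}
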