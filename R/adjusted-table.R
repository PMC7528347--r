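#' Samples-by-variables table with column roles and kinds
#'
#' The central data container: a tibble whose first column is `sample_id`
#' and whose remaining columns each carry a *role* (what the column is for)
#' and a *kind* (its measurement scale). Roles are one of `feature`,
#' `covariate`, `indicator`, `residual_target`, `target`; kinds are one of
#' `continuous`, `binary`, `ordinal`, `nominal`. All non-nominal columns must
#' be numeric and complete (missing values are rejected, not imputed);
#' nominal columns may be character and exist only until they are encoded.
#'
#' @param data A data frame. If it has a `sample_id` column that is used as
#'   the identifier; otherwise the first column is taken as the identifier.
#' @param roles Named character vector mapping every data column to a role.
#' @param kinds Named character vector mapping every data column to a kind.
#' @return A tibble of class `adjusted_table` with `col_roles` and
#'   `col_kinds` attributes.
#' @examples
#' tab <- adjusted_table(
#'   data.frame(sample_id = c("a", "b", "c"), g1 = 1:3, batch = c(0, 1, 0), y = c(2, 4, 6)),
#'   roles = c(g1 = "feature", batch = "covariate", y = "target"),
#'   kinds = c(g1 = "continuous", batch = "binary", y = "continuous")
#' )
#' col_roles(tab)
#' @export
adjusted_table <- function(data, roles, kinds) {
  data <- as_tibble(data)
  id_col <- if ("sample_id" %in% names(data)) "sample_id" else names(data)[1]
  data <- dplyr::rename(data, sample_id = dplyr::all_of(id_col))
  data <- dplyr::relocate(data, "sample_id")
  data$sample_id <- as.character(data$sample_id)
  value_cols <- setdiff(names(data), "sample_id")
  roles <- unlist(roles)
  kinds <- unlist(kinds)
  validate_roles_kinds(value_cols, roles, kinds)
  out <- structure(data,
    col_roles = roles[value_cols], col_kinds = kinds[value_cols],
    class = c("adjusted_table", class(tibble()))
  )
  validate_adjusted_table(out)
  out
}

valid_roles <- c("feature", "covariate", "indicator", "residual_target", "target")
valid_kinds <- c("continuous", "binary", "ordinal", "nominal")

validate_roles_kinds <- function(value_cols, roles, kinds) {
  missing_r <- setdiff(value_cols, names(roles))
  if (length(missing_r) > 0) {
    abort(sprintf("no role declared for column(s): %s", toString(missing_r)))
  }
  missing_k <- setdiff(value_cols, names(kinds))
  if (length(missing_k) > 0) {
    abort(sprintf("no kind declared for column(s): %s", toString(missing_k)))
  }
  extra <- setdiff(names(roles), value_cols)
  if (length(extra) > 0) {
    abort(sprintf("role declared for absent column(s): %s", toString(extra)))
  }
  bad_r <- setdiff(unique(roles), valid_roles)
  if (length(bad_r) > 0) abort(sprintf("invalid role(s): %s", toString(bad_r)))
  bad_k <- setdiff(unique(kinds), valid_kinds)
  if (length(bad_k) > 0) abort(sprintf("invalid kind(s): %s", toString(bad_k)))
}

validate_adjusted_table <- function(x, allow_na_residuals = TRUE) {
  roles <- col_roles(x)
  kinds <- col_kinds(x)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample IDs: %s", toString(unique(dup))))
  }
  n_target <- sum(roles == "target")
  if (n_target > 1) abort("more than one column with role 'target'")
  has_residuals <- any(roles == "residual_target")
  if (n_target == 0 && !has_residuals) {
    abort("table needs exactly one 'target' column (or residual_target columns)")
  }
  for (col in names(roles)) {
    v <- x[[col]]
    if (kinds[[col]] != "nominal") {
      if (!is.numeric(v)) {
        abort(sprintf("column '%s' is declared %s but is not numeric", col, kinds[[col]]))
      }
      na_ok <- allow_na_residuals && roles[[col]] == "residual_target"
      if (!na_ok && anyNA(v)) {
        abort(sprintf(
          "missing values in column '%s' (first at row %d)", col, which(is.na(v))[1]
        ))
      }
    } else if (anyNA(v)) {
      abort(sprintf("missing values in nominal column '%s'", col))
    }
  }
  invisible(x)
}

#' @rdname adjusted_table
#' @param x An `adjusted_table`.
#' @export
col_roles <- function(x) attr(x, "col_roles", exact = TRUE)

#' @rdname adjusted_table
#' @export
col_kinds <- function(x) attr(x, "col_kinds", exact = TRUE)

#' @rdname adjusted_table
#' @export
feature_cols <- function(x) names(which(col_roles(x) == "feature"))

#' @rdname adjusted_table
#' @export
covariate_cols <- function(x) names(which(col_roles(x) == "covariate"))

#' @rdname adjusted_table
#' @export
target_col <- function(x) {
  tc <- names(which(col_roles(x) == "target"))
  if (length(tc) == 0) NULL else tc
}

# Rebuild metadata after adding/removing/renaming value columns.
# `roles`/`kinds` supply entries for new columns; existing entries carry over.
set_table_meta <- function(data, roles, kinds) {
  data <- as_tibble(data)
  value_cols <- setdiff(names(data), "sample_id")
  structure(data,
    col_roles = roles[value_cols], col_kinds = kinds[value_cols],
    class = c("adjusted_table", class(tibble()))
  )
}

# Keep a subset of value columns (sample_id always retained), metadata intact.
keep_columns <- function(x, cols) {
  roles <- col_roles(x)
  kinds <- col_kinds(x)
  set_table_meta(x[, c("sample_id", cols)], roles, kinds)
}

#' @export
print.adjusted_table <- function(x, ...) {
  roles <- col_roles(x)
  cat(sprintf(
    "# adjusted_table: %d samples x %d columns (%d features, %d covariates)\n",
    nrow(x), length(roles), sum(roles == "feature"), sum(roles == "covariate")
  ))
  NextMethod()
}

#' Read a delimited samples-by-variables table
#'
#' Reads a CSV/TSV file (delimiter chosen from the extension: `.csv` comma,
#' `.tsv`/`.txt` tab) with a mandatory header whose first column is the
#' sample identifier, and attaches the declared roles and kinds.
#'
#' @param path Path to the delimited file.
#' @param role_spec A data frame with columns `column`, `role`, `kind`
#'   declaring every value column, or a named list of `c(role, kind)` pairs.
#' @return An [adjusted_table].
#' @seealso [write_table()]
#' @export
read_table <- function(path, role_spec) {
  spec <- normalize_role_spec(role_spec)
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2) abort("table must have a sample-ID column plus data columns")
  absent <- setdiff(spec$column, names(raw))
  if (length(absent) > 0) {
    abort(sprintf("declared column(s) not present in %s: %s", path, toString(absent)))
  }
  raw <- raw[, c(names(raw)[1], spec$column)]
  nominal <- spec$column[spec$kind == "nominal"]
  for (col in setdiff(spec$column, nominal)) {
    v <- raw[[col]]
    if (is.character(v)) {
      v[v %in% c("", "NA")] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
      }
      raw[[col]] <- num
    }
  }
  adjusted_table(raw,
    roles = stats::setNames(spec$role, spec$column),
    kinds = stats::setNames(spec$kind, spec$column)
  )
}

normalize_role_spec <- function(role_spec) {
  if (is.data.frame(role_spec)) {
    stopifnot(all(c("column", "role", "kind") %in% names(role_spec)))
    return(as_tibble(role_spec[, c("column", "role", "kind")]))
  }
  tibble(
    column = names(role_spec),
    role = vapply(role_spec, `[[`, character(1), 1L),
    kind = vapply(role_spec, `[[`, character(1), 2L)
  )
}

read_delim_auto <- function(path) {
  # base strtod parsing is bit-exact on round-trips (fast multi-threaded
  # parsers are not); every column comes in as character and is converted
  # against the declared kinds afterwards
  raw <- utils::read.table(path,
    sep = delim_for(path), header = TRUE, check.names = FALSE,
    colClasses = "character", quote = "\"", comment.char = ""
  )
  as_tibble(raw)
}

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t",
    abort(sprintf("cannot infer delimiter from extension '.%s'", ext))
  )
}

#' Write an adjusted table to a delimited file
#'
#' Values round-trip bit-exactly through [read_table()] (doubles are written
#' with shortest round-trip precision). Role/kind metadata is not embedded in
#' the file; supply the same `role_spec` when re-reading.
#'
#' @param x An [adjusted_table] (or plain data frame).
#' @param path Output path; delimiter chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  out <- as_tibble(as.data.frame(x))
  # 17 significant digits round-trip IEEE doubles exactly
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  readr::write_delim(out, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Extract the role/kind declaration of a table as a tibble
#'
#' Convenience for re-reading a written table with the same metadata.
#'
#' @param x An [adjusted_table].
#' @return A tibble with columns `column`, `role`, `kind`.
#' @export
role_spec_of <- function(x) {
  roles <- col_roles(x)
  tibble(column = names(roles), role = unname(roles), kind = unname(col_kinds(x)[names(roles)]))
}
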