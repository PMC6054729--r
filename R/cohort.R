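#' Construct a two-group cohort table
#'
#' The central data container: a rectangular table of `n1 + n2` units with a
#' two-level group index and `K` typed outcome columns. Missing cells are
#' stored as `NA` and tracked per variable; all downstream tests delete
#' incomplete units per variable (valid under MCAR missingness).
#'
#' @param groups Integer vector of group indices, values in `{1, 2}`, one per
#'   unit. Both groups must be non-empty.
#' @param data A `data.frame` of outcome columns (one per spec; numeric or
#'   character). `NA` marks a missing cell.
#' @param specs List of [variable_spec()] objects, one per outcome column.
#' @param group_labels Character vector of length 2: the original labels of
#'   groups 1 and 2 (metadata only).
#'
#' @return An object of class `"cohort_table"` with elements `groups`,
#'   `data`, `specs`, `group_labels`, `n1`, `n2`.
#' @export
cohort_table <- function(groups, data, specs,
                         group_labels = c("1", "2")) {
  specs <- check_specs(specs)
  groups <- as.integer(groups)
  if (any(!groups %in% c(1L, 2L)))
    stop("group indices must be 1 or 2", call. = FALSE)
  n1 <- sum(groups == 1L); n2 <- sum(groups == 2L)
  if (n1 == 0L || n2 == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (nrow(data) != length(groups))
    stop("'data' must have one row per unit", call. = FALSE)
  missing_cols <- setdiff(names(specs), names(data))
  if (length(missing_cols))
    stop("columns missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- data[names(specs)]
  for (s in specs) {
    col <- data[[s$name]]
    if (s$kind == "numeric") {
      data[[s$name]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      bad <- which(!is.na(col) & !col %in% s$levels)
      if (length(bad))
        stop(sprintf(
          "value '%s' in row %d of column '%s' is not a declared level",
          col[bad[1]], bad[1], s$name), call. = FALSE)
      data[[s$name]] <- col
    }
  }
  structure(list(groups = groups, data = data, specs = specs,
                 group_labels = as.character(group_labels),
                 n1 = n1, n2 = n2),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d units (%s: %d, %s: %d), %d variables, %d missing cells\n",
    x$n1 + x$n2, x$group_labels[1], x$n1, x$group_labels[2], x$n2,
    length(x$specs), sum(is.na(as.matrix(x$data)))))
  invisible(x)
}

#' Missingness mask of a cohort table
#'
#' @param table A [cohort_table()].
#' @return Logical matrix, units x variables; `TRUE` where the cell is missing.
#' @export
missing_mask <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  m <- vapply(table$data, is.na, logical(nrow(table$data)))
  m <- matrix(m, nrow = nrow(table$data),
              dimnames = list(NULL, names(table$data)))
  m
}

#' Read a cohort table from CSV
#'
#' Expects an RFC-4180 CSV with a header row, one grouping column with exactly
#' two observed levels, and one column per variable spec. Cells equal to one
#' of `na_tokens` (after the empty cell) are treated as missing.
#'
#' @param path CSV file path.
#' @param group_column Name of the grouping column.
#' @param specs List of [variable_spec()] objects.
#' @param group_levels Optional character vector of length 2 giving the group
#'   labels mapped to groups 1 and 2 in that order. By default the
#'   lexicographically smaller observed label becomes group 1.
#' @param na_tokens Strings treated as missing; default empty cell and `"NA"`.
#'
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path, group_column, specs,
                            group_levels = NULL,
                            na_tokens = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  specs <- check_specs(specs)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!group_column %in% names(raw))
    stop("group column '", group_column, "' not found", call. = FALSE)
  absent <- setdiff(names(specs), names(raw))
  if (length(absent))
    stop("columns missing from file: ", paste(absent, collapse = ", "),
         call. = FALSE)

  glab <- raw[[group_column]]
  lev <- sort(unique(glab))
  if (length(lev) != 2L)
    stop("group column must have exactly two observed levels, found ",
         length(lev), ": ", paste(lev, collapse = ", "), call. = FALSE)
  if (!is.null(group_levels)) {
    if (!setequal(group_levels, lev))
      stop("'group_levels' must be a permutation of the observed labels",
           call. = FALSE)
    lev <- group_levels
  }
  groups <- ifelse(glab == lev[1], 1L, 2L)

  data <- raw[names(specs)]
  for (nm in names(data)) {
    col <- data[[nm]]
    col[col %in% na_tokens] <- NA_character_
    if (specs[[nm]]$kind == "numeric") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in row %d of column '%s'",
                     col[bad[1]], bad[1], nm), call. = FALSE)
      data[[nm]] <- num
    } else {
      data[[nm]] <- col
    }
  }
  cohort_table(groups, data, specs, group_labels = lev)
}

#' Write a cohort table to CSV
#'
#' Numeric values are written with 17 significant digits so that reading the
#' file back reproduces the table exactly; missing cells are written as the
#' empty string.
#'
#' @param table A [cohort_table()].
#' @param path Output file path.
#' @param group_column Name for the grouping column.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path, group_column = "group") {
  stopifnot(inherits(table, "cohort_table"))
  out <- data.frame(table$group_labels[table$groups],
                    stringsAsFactors = FALSE)
  names(out) <- group_column
  for (nm in names(table$data)) {
    col <- table$data[[nm]]
    txt <- if (is.numeric(col)) sprintf("%.17g", col) else col
    txt[is.na(col)] <- ""
    out[[nm]] <- txt
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Complete cases of one variable, split by group
#'
#' Units missing this variable are dropped for this variable only
#' (per-variable casewise deletion); all other units are retained.
#'
#' @param table A [cohort_table()].
#' @param variable Variable name.
#' @return List with components `x1` and `x2`, the non-missing values in
#'   groups 1 and 2.
#' @export
extract_complete <- function(table, variable) {
  stopifnot(inherits(table, "cohort_table"))
  if (!variable %in% names(table$data))
    stop("unknown variable: ", variable, call. = FALSE)
  col <- table$data[[variable]]
  keep <- !is.na(col)
  x1 <- col[keep & table$groups == 1L]
  x2 <- col[keep & table$groups == 2L]
  if (length(x1) == 0L || length(x2) == 0L)
    stop("variable '", variable,
         "' has no observed values in one group (degenerate)", call. = FALSE)
  list(x1 = x1, x2 = x2)
}

#' Per-group summary of one variable
#'
#' Numeric variables are summarized by mean and sample standard deviation
#' (denominator `n - 1`); categorical variables by the percentage of each
#' declared level, summing to 100 per group. A numeric group of a single
#' observation reports `NA` for the standard deviation rather than zero.
#'
#' @param x1,x2 Group value vectors (as from [extract_complete()]).
#' @param spec The variable's [variable_spec()].
#' @return For numeric variables a list with `kind`, `n1`, `n2`, `mean1`,
#'   `sd1`, `mean2`, `sd2`; for categorical variables a list with `kind`,
#'   `n1`, `n2`, `pct1`, `pct2` (named numeric vectors over the levels).
#' @export
summarize_variable <- function(x1, x2, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  if (!length(x1) || !length(x2))
    stop("both groups must be non-empty", call. = FALSE)
  if (spec$kind == "numeric") {
    sd1 <- if (length(x1) > 1L) stats::sd(x1) else NA_real_
    sd2 <- if (length(x2) > 1L) stats::sd(x2) else NA_real_
    list(kind = "numeric", n1 = length(x1), n2 = length(x2),
         mean1 = mean(x1), sd1 = sd1, mean2 = mean(x2), sd2 = sd2)
  } else {
    pct <- function(x) {
      cnt <- table(factor(x, levels = spec$levels))
      100 * as.vector(cnt) / length(x)
    }
    p1 <- stats::setNames(pct(x1), spec$levels)
    p2 <- stats::setNames(pct(x2), spec$levels)
    list(kind = "categorical", n1 = length(x1), n2 = length(x2),
         pct1 = p1, pct2 = p2)
  }
}
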