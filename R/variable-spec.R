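#' Declare an outcome variable
#'
#' A variable specification records the name and kind of one outcome column
#' of a cohort table. Categorical variables carry an ordered list of legal
#' category labels; every non-missing value in the data must be one of them.
#'
#' @param name Column name, a non-empty string.
#' @param kind Either `"numeric"` or `"categorical"`.
#' @param levels Character vector of category labels (categorical only,
#'   at least two). Must be `NULL` for numeric variables.
#'
#' @return An object of class `"variable_spec"`.
#' @examples
#' variable_spec("diagnosis_age", "numeric")
#' variable_spec("smoking_habit", "categorical", levels = c("yes", "no"))
#' @export
variable_spec <- function(name, kind = c("numeric", "categorical"),
                          levels = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop("categorical variable '", name, "' needs >= 2 levels",
           call. = FALSE)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop("duplicate levels for variable '", name, "'", call. = FALSE)
  } else if (!is.null(levels)) {
    stop("numeric variable '", name, "' must not declare levels",
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, levels = levels),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  lv <- if (is.null(x$levels)) "" else
    paste0(" [", paste(x$levels, collapse = ", "), "]")
  cat(sprintf("<variable_spec> %s: %s%s\n", x$name, x$kind, lv))
  invisible(x)
}

# Validate a list of variable_spec objects; names must be unique.
check_specs <- function(specs) {
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), what = "variable_spec")
  if (!length(specs) || !all(ok))
    stop("'specs' must be a list of variable_spec objects", call. = FALSE)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate variable names in specs: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(specs) <- nm
  specs
}

#' Read or write variable specifications as YAML
#'
#' The on-disk format is a list of mappings with keys `name`, `kind` and
#' (for categorical variables) `levels`.
#'
#' @param path File path.
#' @param specs List of [variable_spec()] objects.
#' @return `read_variable_specs()` returns a named list of specs;
#'   `write_variable_specs()` returns `path` invisibly.
#' @export
read_variable_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$variables)) raw <- raw$variables
  specs <- lapply(raw, function(v)
    variable_spec(v$name, v$kind,
                  levels = if (identical(v$kind, "categorical"))
                    as.character(v$levels)))
  check_specs(specs)
}

#' @rdname read_variable_specs
#' @export
write_variable_specs <- function(specs, path) {
  specs <- check_specs(specs)
  out <- lapply(unname(specs), function(s) {
    v <- list(name = s$name, kind = s$kind)
    if (!is.null(s$levels)) v$levels <- as.list(s$levels)
    v
  })
  yaml::write_yaml(list(variables = out), path)
  invisible(path)
}
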