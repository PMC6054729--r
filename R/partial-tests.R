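#' Absolute difference of group means
#'
#' The numeric partial-test statistic: `|mean(x1) - mean(x2)|`. It is
#' two-sided because the sub-alternative is distributional inequality in
#' either direction, and unstandardized; a studentized variant is available
#' through the `studentize` option of [run_analysis()].
#'
#' @param x1,x2 Non-empty numeric vectors.
#' @return The statistic (units of the variable).
#' @examples
#' mean_diff_statistic(c(1, 3), c(2, 6))  # |2 - 4| = 2
#' @export
mean_diff_statistic <- function(x1, x2) {
  if (!length(x1) || !length(x2))
    stop("both groups must be non-empty", call. = FALSE)
  abs(mean(x1) - mean(x2))
}

#' Likelihood-ratio G statistic of a 2 x L contingency table
#'
#' `G = 2 * sum O * ln(O / E)` over cells, with expected counts
#' `E = row_total * col_total / grand_total` and the convention
#' `0 * ln(0 / E) = 0`. Columns with zero total contribute nothing. Used as
#' the categorical partial-test statistic, referred to its permutation null
#' rather than the asymptotic chi-square.
#'
#' @param counts Numeric matrix with 2 rows (groups) and one column per
#'   category; non-negative counts, both row totals >= 1.
#' @return The G statistic (dimensionless).
#' @examples
#' lr_statistic(rbind(c(5, 5), c(10, 10)))   # identical proportions: 0
#' lr_statistic(rbind(c(10, 0), c(0, 10)))   # 40 * log(2)
#' @export
lr_statistic <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("'counts' must have 2 rows", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rt <- rowSums(counts)
  if (any(rt < 1)) stop("each group must contain at least one unit",
                        call. = FALSE)
  ct <- colSums(counts)
  keep <- ct > 0
  if (!any(keep)) stop("all counts are zero", call. = FALSE)
  O <- counts[, keep, drop = FALSE]
  E <- outer(rt, ct[keep]) / sum(rt)
  terms <- O * log(O / E)
  terms[O == 0] <- 0
  2 * sum(terms)
}

# --- vectorized permutation engines ----------------------------------------
#
# A1 is the B x m 0/1 indicator of membership in group 1 among the m pooled
# complete cases of one variable; row 1 is the observed labeling. Rows where
# a permuted split leaves one group empty (possible only under missingness)
# get statistic -Inf: they never count as extreme and take significance
# level 1 in the NPC transform.

perm_stats_numeric <- function(v, A1, studentize = FALSE) {
  m <- length(v)
  m1 <- as.vector(A1 %*% rep(1, m))
  m2 <- m - m1
  s1 <- as.vector(A1 %*% v)
  tot <- sum(v)
  ok <- m1 > 0 & m2 > 0
  t <- rep(-Inf, nrow(A1))
  d <- s1[ok] / m1[ok] - (tot - s1[ok]) / m2[ok]
  if (studentize) {
    q1 <- as.vector(A1 %*% (v * v))
    totq <- sum(v * v)
    ss1 <- q1[ok] - s1[ok]^2 / m1[ok]
    ss2 <- (totq - q1[ok]) - (tot - s1[ok])^2 / m2[ok]
    df <- m1[ok] + m2[ok] - 2
    s2 <- (ss1 + ss2) / pmax(df, 1)
    se <- sqrt(pmax(s2, 0) * (1 / m1[ok] + 1 / m2[ok]))
    t[ok] <- ifelse(se > 0, abs(d) / se, ifelse(abs(d) > 0, Inf, 0))
  } else {
    t[ok] <- abs(d)
  }
  t
}

perm_stats_lr <- function(values, levels, A1) {
  f <- factor(values, levels = levels)
  ct <- as.vector(table(f))
  keep <- ct > 0
  if (sum(keep) < 2L) return(rep(0, nrow(A1)))   # single observed level
  Z <- vapply(levels[keep], function(l) as.double(f == l),
              double(length(values)))
  ctk <- ct[keep]
  m <- length(values)
  O1 <- A1 %*% Z                                  # B x L counts in group 1
  m1 <- rowSums(O1)
  m2 <- m - m1
  O2 <- sweep(-O1, 2L, ctk, `+`)                  # col totals are invariant
  E1 <- (m1 / m) %o% ctk
  E2 <- (m2 / m) %o% ctk
  xlogy <- function(O, E) {
    r <- O * log(O / E)
    r[O == 0] <- 0
    r
  }
  g <- 2 * (rowSums(xlogy(O1, E1)) + rowSums(xlogy(O2, E2)))
  g[m1 == 0 | m2 == 0] <- -Inf
  g
}

# Map a canonical assignment matrix (first n1 columns = observed group 1) to
# unit order, then restrict to the complete cases of one variable.
align_assignments <- function(A, groups) {
  pooled <- c(which(groups == 1L), which(groups == 2L))
  out <- A
  out[, pooled] <- A
  out
}

#' Partial permutation test of one variable
#'
#' Extracts the variable's complete cases, computes the observed statistic
#' (absolute mean difference for numeric variables, likelihood-ratio G for
#' categorical ones) and recomputes it under every group reassignment of the
#' scheme, restricted to the complete cases. The raw p-value is the fraction
#' of assignments with a statistic at least as large as the observed one.
#'
#' A degenerate variable (only one observed level, or all values of one group
#' missing) yields a flagged result with `raw_p = 1` and a warning rather
#' than an error, so cohort-wide runs are not interrupted.
#'
#' @param table A [cohort_table()].
#' @param variable Variable name.
#' @param spec The variable's [variable_spec()]; defaults to the one stored
#'   in the table.
#' @param scheme A [perm_scheme()].
#' @param assignments Optional pre-generated unit-level assignment matrix in
#'   table order (as used by [run_analysis()] to share one permutation
#'   stream across variables); if `NULL`, assignments are generated from
#'   `scheme` and aligned to the table's unit order.
#' @param studentize Use the pooled-variance t statistic instead of the raw
#'   mean difference for numeric variables. Default `FALSE`.
#' @param A1 Optional precomputed 0/1 double matrix `(assignments == 1) * 1`,
#'   supplied by [run_analysis()] to avoid recomputing it per variable.
#'
#' @return Object of class `"partial_test"`: list with `variable`, `kind`,
#'   `t_obs`, `t_perm` (first element equals `t_obs`), `raw_p`, `n1`, `n2`
#'   (complete-case group sizes), `B`, `degenerate`.
#' @export
partial_test <- function(table, variable, spec = NULL,
                         scheme = perm_scheme(), assignments = NULL,
                         studentize = FALSE, A1 = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (is.null(spec)) spec <- table$specs[[variable]]
  if (is.null(spec)) stop("unknown variable: ", variable, call. = FALSE)

  if (is.null(assignments)) {
    A <- generate_assignments(table$n1, table$n2, scheme)
    assignments <- align_assignments(A, table$groups)
  }
  col <- table$data[[variable]]
  keep <- !is.na(col)
  g_obs <- table$groups[keep]
  v <- col[keep]

  degenerate <- FALSE
  reason <- NULL
  if (!any(g_obs == 1L) || !any(g_obs == 2L)) {
    degenerate <- TRUE
    reason <- "one group entirely missing"
  } else if (length(unique(v)) < 2L) {
    degenerate <- TRUE
    reason <- "single observed value"
  }
  B <- nrow(assignments)
  if (degenerate) {
    warning("variable '", variable, "' is degenerate (", reason,
            "); raw_p set to 1", call. = FALSE)
    t_perm <- rep(0, B)
    res <- list(variable = variable, kind = spec$kind, t_obs = 0,
                t_perm = t_perm, raw_p = 1,
                n1 = sum(g_obs == 1L), n2 = sum(g_obs == 2L),
                B = B, seed = scheme$seed, degenerate = TRUE)
    class(res) <- "partial_test"
    return(res)
  }

  A1sub <- if (is.null(A1)) {
    (assignments[, keep, drop = FALSE] == 1L) * 1
  } else if (all(keep)) A1 else A1[, keep, drop = FALSE]
  t_perm <- if (spec$kind == "numeric") {
    perm_stats_numeric(as.numeric(v), A1sub, studentize = studentize)
  } else {
    perm_stats_lr(v, spec$levels, A1sub)
  }
  t_obs <- t_perm[1L]
  raw_p <- pvalue_from_distribution(t_obs, t_perm, tie_tol = scheme$tie_tol)
  res <- list(variable = variable, kind = spec$kind, t_obs = t_obs,
              t_perm = t_perm, raw_p = raw_p,
              n1 = sum(g_obs == 1L), n2 = sum(g_obs == 2L),
              B = B, seed = scheme$seed, degenerate = FALSE)
  class(res) <- "partial_test"
  res
}

#' @export
print.partial_test <- function(x, ...) {
  cat(sprintf("<partial_test> %s (%s): T = %.6g, raw p = %.4f (B = %d)%s\n",
              x$variable, x$kind, x$t_obs, x$raw_p, x$B,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
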