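#' Significance-level transform of a permutation statistic column
#'
#' Converts one partial test's permuted statistics into within-column
#' significance levels: `lambda[b] = #\{b' : T[b'] >= T[b] - tol\} / B`, the
#' permutation survival level of each assignment's statistic within its own
#' column. This is the per-assignment analogue of a p-value and the quantity
#' the NPC combining functions consume; values lie in `[1/B, 1]`.
#'
#' @param t_column Numeric vector of length `B` (one statistic per
#'   assignment).
#' @param tie_tol Relative tie tolerance; default `1e-12`.
#' @return Numeric vector of significance levels, same length as `t_column`.
#' @examples
#' significance_transform(c(3, 1, 2))  # 1/3, 1, 2/3
#' @export
significance_transform <- function(t_column, tie_tol = 1e-12) {
  B <- length(t_column)
  if (B < 2L) stop("need at least 2 assignments", call. = FALSE)
  lam <- rep(1, B)
  fin <- is.finite(t_column)
  if (any(fin)) {
    s <- sort(t_column[fin])
    thr <- t_column[fin] - tie_tol * pmax(1, abs(t_column[fin]))
    # count of sorted values < threshold, via left-open interval lookup
    n_less <- findInterval(thr, s, left.open = TRUE)
    lam[fin] <- (length(s) - n_less) / B
  }
  lam
}

#' Combine partial significance levels into one statistic
#'
#' The three classical NPC combining functions, all significant for large
#' values: Fisher `psi = -2 * sum(log(lambda))`, Liptak
#' `psi = sum(qnorm(1 - lambda))`, Tippett `psi = max(1 - lambda)`. For
#' Fisher and Liptak, `lambda` is clamped into `[clamp, 1 - clamp]` so the
#' statistic stays finite at the attainable extremes `1/B` and `1`; the
#' recommended clamp is `1 / (2 * B)`, which never reorders attainable
#' values. `clamp = 0` disables clamping.
#'
#' @param lambdas Numeric vector of `K` significance levels in `(0, 1]`.
#' @param method `"fisher"`, `"liptak"` or `"tippett"`.
#' @param clamp Clamping constant for the log/quantile transforms; default 0.
#' @return The combined statistic (scalar).
#' @examples
#' combine(c(0.1, 0.2))                         # -2*(log(.1)+log(.2))
#' combine(c(0.2, 0.5), method = "tippett")     # 0.8
#' @export
combine <- function(lambdas, method = c("fisher", "liptak", "tippett"),
                    clamp = 0) {
  method <- match.arg(method)
  if (any(lambdas <= 0 | lambdas > 1))
    stop("significance levels must lie in (0, 1]", call. = FALSE)
  as.vector(combine_rows(matrix(lambdas, nrow = 1), method, clamp))
}

# Row-wise combining of a B x K significance-level matrix.
combine_rows <- function(L, method, clamp) {
  if (clamp > 0) L <- pmin(pmax(L, clamp), 1 - clamp)
  switch(method,
    fisher = -2 * rowSums(log(L)),
    liptak = rowSums(stats::qnorm(1 - L)),
    tippett = {
      m <- 1 - L[, 1]
      if (ncol(L) > 1L)
        for (j in 2:ncol(L)) m <- pmax(m, 1 - L[, j])
      m
    })
}

#' Nonparametric combination of dependent partial tests
#'
#' Combines `K` partial permutation tests computed on one shared assignment
#' sequence into a single global test of the intersection null (all variables
#' equidistributed across groups) against the union alternative (at least one
#' differs). The `B x K` matrix of permuted statistics is column-wise
#' transformed to significance levels, each row is combined into one
#' statistic, and the combined p-value is the permutation survival level of
#' the observed (first) row. Because every row is one and the same group
#' reassignment applied to all variables, the dependence among the partial
#' tests is carried through without modeling it.
#'
#' @param partials List of `K` [partial_test()] results sharing one scheme
#'   (equal `B` and seed).
#' @param method Combining function, see [combine()]. Default `"fisher"`.
#' @param tie_tol Relative tie tolerance; default `1e-12`.
#' @param clamp Clamp for log/quantile combiners; default `1 / (2 * B)`.
#' @return Object of class `"npc_result"`: list with `method`, `K`, `B`,
#'   `partial_raw_p` (named), `lambda_obs`, `psi_obs`, `psi_perm`,
#'   `combined_p`.
#' @export
npc_global_test <- function(partials,
                            method = c("fisher", "liptak", "tippett"),
                            tie_tol = 1e-12, clamp = NULL) {
  method <- match.arg(method)
  if (inherits(partials, "partial_test")) partials <- list(partials)
  ok <- vapply(partials, inherits, logical(1), what = "partial_test")
  if (!length(partials) || !all(ok))
    stop("'partials' must be a list of partial_test results", call. = FALSE)
  Bs <- vapply(partials, `[[`, integer(1), "B")
  if (length(unique(Bs)) != 1L)
    stop("partial tests use different numbers of assignments",
         call. = FALSE)
  seeds <- vapply(partials, `[[`, integer(1), "seed")
  if (length(unique(seeds)) != 1L)
    stop("partial tests were computed on different permutation streams",
         call. = FALSE)
  B <- Bs[1]
  K <- length(partials)
  if (is.null(clamp)) clamp <- 1 / (2 * B)

  Tm <- vapply(partials, `[[`, double(B), "t_perm")
  L <- apply(Tm, 2L, significance_transform, tie_tol = tie_tol)
  psi_perm <- combine_rows(L, method, clamp)
  psi_obs <- psi_perm[1L]
  combined_p <- pvalue_from_distribution(psi_obs, psi_perm,
                                         tie_tol = tie_tol)
  vars <- vapply(partials, `[[`, character(1), "variable")
  res <- list(method = method, K = K, B = B,
              partial_raw_p = stats::setNames(
                vapply(partials, `[[`, double(1), "raw_p"), vars),
              lambda_obs = stats::setNames(L[1L, ], vars),
              psi_obs = psi_obs, psi_perm = psi_perm,
              combined_p = combined_p)
  class(res) <- "npc_result"
  res
}

#' @export
print.npc_result <- function(x, ...) {
  cat(sprintf(
    "<npc_result> %s combination of %d partial tests (B = %d)\n  psi = %.6g, combined p = %s\n",
    x$method, x$K, x$B, x$psi_obs, format_pvalue(x$combined_p, 4, x$B)))
  invisible(x)
}
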