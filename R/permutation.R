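# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Define a permutation scheme
#'
#' Controls how group-label reassignments are produced: by Conditional Monte
#' Carlo (`B` uniform random reassignments including the observed one) or by
#' exhaustive enumeration of all `choose(n1 + n2, n1)` distinct splits. With
#' `mode = "auto"` enumeration is used whenever the number of distinct splits
#' does not exceed `exact_threshold`.
#'
#' @param B Number of Monte Carlo permutations (>= 2), the observed labeling
#'   included. Default 10000.
#' @param seed Integer seed for the pseudo-random stream.
#' @param exact_threshold Largest number of distinct splits for which
#'   exhaustive enumeration is used in `"auto"` mode. Default 20000.
#' @param mode `"auto"`, `"random"` or `"exact"`.
#' @param tie_tol Relative tolerance for declaring two statistic values tied
#'   when counting exceedances. Default `1e-12`.
#'
#' @return An object of class `"perm_scheme"`.
#' @export
perm_scheme <- function(B = 10000L, seed = 1L, exact_threshold = 20000L,
                        mode = c("auto", "random", "exact"),
                        tie_tol = 1e-12) {
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (is.na(B) || B < 2L) stop("'B' must be >= 2", call. = FALSE)
  if (tie_tol < 0) stop("'tie_tol' must be non-negative", call. = FALSE)
  structure(list(B = B, seed = as.integer(seed),
                 exact_threshold = as.double(exact_threshold),
                 mode = mode, tie_tol = tie_tol),
            class = "perm_scheme")
}

#' @export
print.perm_scheme <- function(x, ...) {
  cat(sprintf("<perm_scheme> B = %d, seed = %d, mode = %s (exact <= %g splits)\n",
              x$B, x$seed, x$mode, x$exact_threshold))
  invisible(x)
}

#' Generate group-label reassignments
#'
#' Produces the matrix of group labelings over which permutation
#' distributions are computed. Row 1 is always the observed (identity)
#' labeling: the first `n1` units in group 1, the rest in group 2. In random
#' (Conditional Monte Carlo) mode the remaining `B - 1` rows are independent
#' uniform shuffles of the label vector; duplicate splits are allowed, as
#' deduplication would bias the p-value estimator. In exact mode all
#' `choose(n1 + n2, n1)` distinct splits are returned, identity first.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @param scheme A [perm_scheme()].
#' @return Integer matrix with `n1 + n2` columns and values in `{1, 2}`; one
#'   row per assignment. Attribute `"mode"` records which mode was used.
#' @examples
#' generate_assignments(2, 2, perm_scheme(mode = "exact"))  # all 6 splits
#' @export
generate_assignments <- function(n1, n2, scheme = perm_scheme()) {
  stopifnot(inherits(scheme, "perm_scheme"))
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 < 1L) stop("group sizes must be >= 1", call. = FALSE)
  n <- n1 + n2
  n_splits <- choose(n, n1)
  mode <- scheme$mode
  if (mode == "auto")
    mode <- if (n_splits <= scheme$exact_threshold) "exact" else "random"
  if (mode == "exact" && n_splits > scheme$exact_threshold)
    stop("exact enumeration requested but choose(n, n1) = ", n_splits,
         " exceeds exact_threshold", call. = FALSE)

  identity <- c(rep(1L, n1), rep(2L, n2))
  if (mode == "exact") {
    sets <- utils::combn(n, n1)          # lexicographic; identity is column 1
    A <- matrix(2L, nrow = ncol(sets), ncol = n)
    A[cbind(rep(seq_len(ncol(sets)), each = n1), as.vector(sets))] <- 1L
  } else {
    A <- matrix(2L, nrow = scheme$B, ncol = n)
    A[1L, ] <- identity
    with_seed(scheme$seed, {
      for (b in 2:scheme$B) A[b, ] <- identity[sample.int(n)]
    })
  }
  attr(A, "mode") <- mode
  A
}

#' Permutation p-value of an observed statistic
#'
#' Estimates `p = #\{b : T_b >= T_obs - tol\} / B` from a permutation
#' distribution that includes the observed assignment's statistic, so the
#' smallest attainable p-value is `1 / B`. Statistics are significant for
#' large values. The tolerance absorbs floating-point noise among
#' permutations of the same sums: `tol = tie_tol * max(1, |T_obs|)`.
#'
#' @param t_obs Observed statistic.
#' @param t_perm Vector of permuted statistics (the observed one among them).
#' @param tie_tol Relative tie tolerance; default `1e-12`.
#' @return p-value in `(0, 1]`.
#' @examples
#' pvalue_from_distribution(4, c(1, 2, 3, 4, 5))  # 0.4
#' @export
pvalue_from_distribution <- function(t_obs, t_perm, tie_tol = 1e-12) {
  if (!length(t_perm)) stop("empty permutation distribution", call. = FALSE)
  tol <- tie_tol * max(1, abs(t_obs))
  sum(t_perm >= t_obs - tol) / length(t_perm)
}
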