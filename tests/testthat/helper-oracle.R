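# Independent brute-force reference implementations, kept deliberately naive
# (explicit loops, no shared code with the package internals). Used as
# oracles for exact-enumeration equivalence checks.

oracle_tie_tol <- function(t) 1e-12 * max(1, abs(t))

oracle_mean_diff <- function(x1, x2) {
  s1 <- 0; for (v in x1) s1 <- s1 + v
  s2 <- 0; for (v in x2) s2 <- s2 + v
  abs(s1 / length(x1) - s2 / length(x2))
}

oracle_lr <- function(x1, x2, levels) {
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  g <- 0
  for (l in levels) {
    o1 <- sum(x1 == l); o2 <- sum(x2 == l)
    ct <- o1 + o2
    if (ct == 0) next
    e1 <- n1 * ct / n; e2 <- n2 * ct / n
    if (o1 > 0) g <- g + o1 * log(o1 / e1)
    if (o2 > 0) g <- g + o2 * log(o2 / e2)
  }
  2 * g
}

# All distinct splits of n pooled units into groups of sizes n1 / n2,
# as a list of group-1 index sets (identity split first).
oracle_splits <- function(n1, n2) {
  sets <- utils::combn(n1 + n2, n1, simplify = FALSE)
  sets
}

# Exact permutation distribution of one variable over all splits.
# values: pooled vector in unit order; obs_idx1: observed group-1 indices.
oracle_exact_stats <- function(values, obs_idx1, kind, levels = NULL) {
  n <- length(values)
  n1 <- length(obs_idx1)
  pooled <- c(obs_idx1, setdiff(seq_len(n), obs_idx1))
  stats <- vapply(oracle_splits(n1, n - n1), function(s) {
    idx1 <- pooled[s]
    x1 <- values[idx1]; x2 <- values[setdiff(seq_len(n), idx1)]
    if (kind == "numeric") oracle_mean_diff(x1, x2)
    else oracle_lr(x1, x2, levels)
  }, double(1))
  stats   # element 1 corresponds to the observed labeling
}

oracle_pvalue <- function(t_obs, t_all) {
  cnt <- 0
  for (t in t_all) if (t >= t_obs - oracle_tie_tol(t_obs)) cnt <- cnt + 1
  cnt / length(t_all)
}

oracle_lambda <- function(t_all) {
  M <- length(t_all)
  out <- numeric(M)
  for (b in seq_len(M)) {
    cnt <- 0
    for (t in t_all) if (t >= t_all[b] - oracle_tie_tol(t_all[b])) cnt <- cnt + 1
    out[b] <- cnt / M
  }
  out
}

oracle_combine <- function(lams, method, clamp) {
  l <- pmin(pmax(lams, clamp), 1 - clamp)
  if (method == "fisher") -2 * sum(log(l))
  else if (method == "liptak") sum(qnorm(1 - l))
  else max(1 - lams)
}

# Full exact NPC over a small cohort_table: returns partial p-values and the
# combined p-value from first principles.
oracle_npc <- function(table, method = "fisher") {
  specs <- table$specs
  obs_idx1 <- which(table$groups == 1L)
  K <- length(specs)
  stat_cols <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    oracle_exact_stats(table$data[[nm]], obs_idx1, s$kind, s$levels)
  })
  M <- length(stat_cols[[1]])
  partial_p <- vapply(stat_cols, function(tc) oracle_pvalue(tc[1], tc),
                      double(1))
  L <- vapply(stat_cols, oracle_lambda, double(M))
  clamp <- if (method == "tippett") 0 else 1 / (2 * M)
  psi <- numeric(M)
  for (b in seq_len(M)) psi[b] <- oracle_combine(L[b, ], method, clamp)
  list(partial_p = setNames(partial_p, names(specs)),
       combined_p = oracle_pvalue(psi[1], psi))
}

# Naive Holm via repeated Bonferroni on the remaining set (independent of the
# package's sort-based implementation).
oracle_holm_decisions <- function(p, alpha) {
  K <- length(p)
  rejected <- logical(K)
  repeat {
    remaining <- which(!rejected)
    if (!length(remaining)) break
    thr <- alpha / length(remaining)
    cand <- remaining[which.min(p[remaining])]
    if (p[cand] < thr) rejected[cand] <- TRUE else break
  }
  rejected
}
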