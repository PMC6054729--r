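#' Bonferroni-Holm step-down decisions
#'
#' The sequentially rejective rule: sort the `K` raw p-values ascending and
#' reject hypotheses in order while `p_(i) < alpha / (K - i + 1)`; at the
#' first `i` with `p_(i) >= alpha / (K - i + 1)` the procedure stops and that
#' hypothesis and all later ones are retained. Controls the familywise error
#' rate at `alpha` and is uniformly more powerful than the classical
#' Bonferroni correction.
#'
#' @param raw_ps Numeric vector of raw p-values in `(0, 1]`.
#' @param alpha Familywise level in `(0, 1)`; default 0.05.
#' @return Logical vector in the input order: `TRUE` where rejected.
#' @export
holm_decisions <- function(raw_ps, alpha = 0.05) {
  check_pvec(raw_ps)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)", call. = FALSE)
  K <- length(raw_ps)
  ord <- order(raw_ps)                     # stable: ties keep input order
  sorted <- raw_ps[ord]
  k <- 0L
  for (i in seq_len(K)) {
    if (sorted[i] < alpha / (K - i + 1)) k <- i else break
  }
  out <- logical(K)
  if (k > 0L) out[ord[seq_len(k)]] <- TRUE
  out
}

#' Holm adjusted p-values
#'
#' The monotone step-down adjustment: with `p_(1) <= ... <= p_(K)`,
#' `q_(i) = max_{j <= i} min(cap, (K - j + 1) * p_(j))`, mapped back to the
#' input order. Rejecting where `q <= alpha` reproduces [holm_decisions()]
#' for every `alpha` below `cap` (up to exact boundary ties). `cap = 0.9999`
#' reproduces the rendering convention of permutation software whose largest
#' expressible raw p-value at `B = 10000` (identity included) is 0.9999.
#'
#' @param raw_ps Numeric vector of raw p-values in `(0, 1]`.
#' @param cap Maximum reported adjusted value; default 1.
#' @return Numeric vector of adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(raw_ps, cap = 1) {
  check_pvec(raw_ps)
  if (cap <= 0) stop("'cap' must be positive", call. = FALSE)
  K <- length(raw_ps)
  ord <- order(raw_ps)
  sorted <- raw_ps[ord]
  q <- cummax(pmin(cap, (K - seq_len(K) + 1) * sorted))
  out <- numeric(K)
  out[ord] <- q
  out
}

#' Full Holm result table
#'
#' @param raw_ps Named (or unnamed) vector of raw p-values.
#' @param alpha Familywise level; default 0.05.
#' @param cap Adjusted-p cap; default 1.
#' @return A `data.frame` with columns `variable`, `raw_p`, `rank_i`
#'   (position in the ascending sort), `adj_p` and `significant` (sequential
#'   rule at `alpha`), in the input order.
#' @export
holm_table <- function(raw_ps, alpha = 0.05, cap = 1) {
  check_pvec(raw_ps)
  K <- length(raw_ps)
  nm <- names(raw_ps)
  if (is.null(nm)) nm <- paste0("V", seq_len(K))
  rank_i <- integer(K)
  rank_i[order(raw_ps)] <- seq_len(K)
  data.frame(variable = nm,
             raw_p = as.vector(raw_ps),
             rank_i = rank_i,
             adj_p = holm_adjust(raw_ps, cap = cap),
             significant = holm_decisions(raw_ps, alpha = alpha),
             stringsAsFactors = FALSE)
}

check_pvec <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  invisible(p)
}
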