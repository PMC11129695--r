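# Independent oracles used by the unit and acceptance tests. These are
# deliberately brute-force and share no code with the package internals.

# Maximum bipartite matching between left and right start frames under
# |delta start| <= tol, by exhaustive recursion. Feasible for <= ~12 events
# per side.
max_matching_oracle <- function(left_starts, right_starts, tol) {
  nr <- length(right_starts)
  best <- function(i, used) {
    if (i > length(left_starts)) return(0L)
    # skip left event i
    res <- best(i + 1L, used)
    for (j in seq_len(nr)) {
      if (!used[j] && abs(left_starts[i] - right_starts[j]) <= tol) {
        used2 <- used
        used2[j] <- TRUE
        res <- max(res, 1L + best(i + 1L, used2))
      }
    }
    res
  }
  best(1L, logical(nr))
}

# Exact two-sided rank-sum p-value by full enumeration of all assignments of
# the pooled ranks to the first group; mirrors the two-sided convention of
# the exact Mann-Whitney test (double the smaller tail, capped at 1).
# Assumes no ties.
ranksum_enum_oracle <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_null <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(w_null <= w_obs)
  p_ge <- mean(w_null >= w_obs)
  p <- if (w_obs > n1 * length(y) / 2) 2 * p_ge else 2 * p_le
  list(W = w_obs, p = min(1, p))
}

# Exact binomial p-values by direct summation of the probability mass:
# one-sided in the direction of the observed deviation; two-sided as the sum
# of all outcomes no more probable than the observed one (with the usual
# tiny relative slack for floating-point equality).
binom_sum_oracle <- function(x, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  rel <- 1 + 1e-07
  p_two <- sum(d[d <= d[x + 1L] * rel])
  p_one <- if (x / n <= p0) sum(d[seq_len(x + 1L)]) else sum(d[(x + 1L):(n + 1L)])
  list(p_one = p_one, p_two = min(1, p_two))
}

# Spearman rho by the classic no-ties closed form 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
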