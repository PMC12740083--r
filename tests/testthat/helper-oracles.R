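# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and stats::dhyper/phyper/p.adjust, which serve as separate
# cross-checks) so that agreement is evidence, not tautology.

# hypergeometric tail probabilities by exhaustive enumeration of draws:
# universe items 1..N, items 1..M marked, enumerate all C(N, n) subsets
enum_hyper <- function(N, M, n) {
  if (n == 0) return(list(k = 0, count = 1, total = 1))
  draws <- utils::combn(N, n)
  k <- colSums(draws <= M)
  list(k = k, total = ncol(draws))
}

enum_p_over <- function(N, M, n, k) {
  e <- enum_hyper(N, M, n)
  sum(e$k >= k) / e$total
}

enum_p_under <- function(N, M, n, k) {
  e <- enum_hyper(N, M, n)
  sum(e$k <= k) / e$total
}

enum_pmf <- function(N, M, n, k) {
  e <- enum_hyper(N, M, n)
  sum(e$k == k) / e$total
}

# literal step-up definition of Benjamini-Hochberg, O(m^2)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# tie-aware Mann-Whitney two-sided p by enumerating which pooled positions
# belong to sample 1, under exchangeability; midranks fixed by the pooled
# multiset; two-sided p = min(1, 2 * min tail), tails including the observed
# rank sum
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ntot <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(ntot, n1)
  w_all <- colSums(matrix(r[subsets], nrow = n1))
  p_low <- mean(w_all <= w_obs + 1e-9)
  p_high <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# all multisets of a given size over the values `vals`
all_multisets <- function(size, vals = 1:3) {
  combs <- utils::combn(length(vals) + size - 1, size)
  apply(combs, 2, function(cols) vals[cols - seq_len(size) + 1], simplify = FALSE)
}
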