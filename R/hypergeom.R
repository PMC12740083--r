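#' Hypergeometric probability mass
#'
#' Probability of observing exactly `k` marked genes when drawing `n` genes
#' without replacement from a universe of `N` genes of which `M` are marked:
#' P(X = k) = C(M, k) C(N - M, n - k) / C(N, n). Computed in log space via
#' log-gamma so large universes (N ~ 2e4) stay exact to double precision.
#' Values of `k` outside the support return 0.
#'
#' @param N Universe size (nonnegative integer).
#' @param M Marked genes in the universe, 0 <= M <= N.
#' @param n Draw size, 0 <= n <= N.
#' @param k Observed marked count; may be a vector.
#' @return Numeric vector of probabilities, same length as `k`.
#' @export
hyper_pmf <- function(N, M, n, k) {
  .check_hyper(N, M, n)
  k <- as.numeric(k)
  lo <- max(0, n - (N - M)); hi <- min(M, n)
  out <- numeric(length(k))
  ok <- !is.na(k) & k == floor(k) & k >= lo & k <= hi
  if (any(ok)) {
    kk <- k[ok]
    out[ok] <- exp(lchoose(M, kk) + lchoose(N - M, n - kk) - lchoose(N, n))
  }
  out
}

.check_hyper <- function(N, M, n) {
  if (any(c(N, M, n) < 0) || M > N || n > N) {
    stop("require 0 <= M <= N and 0 <= n <= N (got N=", N,
         ", M=", M, ", n=", n, ")")
  }
}

# tail sums: always sum the requested tail directly. Every term is positive,
# so there is no cancellation and a tail of 1e-300 keeps full relative
# accuracy; complementing (1 - other tail) would destroy it. The support has
# at most min(M, n) + 1 terms, which is cheap at genome scale. Terms are
# summed from the far end inward (smallest first under unimodality near the
# observed edge) to limit rounding.
.hyper_tail <- function(N, M, n, k, upper) {
  .check_hyper(N, M, n)
  lo <- max(0, n - (N - M)); hi <- min(M, n)
  k <- floor(as.numeric(k))
  # tails are floored at the smallest positive double: an observed k always
  # has positive probability, so an underflowed 0 would violate p in (0, 1]
  if (upper) {
    if (k <= lo) return(1)
    if (k > hi) return(0)
    min(1, max(sum(hyper_pmf(N, M, n, hi:k)), .Machine$double.xmin))
  } else {
    if (k >= hi) return(1)
    if (k < lo) return(0)
    min(1, max(sum(hyper_pmf(N, M, n, lo:k)), .Machine$double.xmin))
  }
}

#' One-tailed over-representation probability P(X >= k)
#'
#' The observed value is included in the tail, matching the one-sided
#' over-representation hypothesis; at the bottom of the support this is 1.
#'
#' @inheritParams hyper_pmf
#' @param k Observed count (scalar).
#' @return P(X >= k).
#' @export
hyper_p_over <- function(N, M, n, k) .hyper_tail(N, M, n, k, upper = TRUE)

#' One-tailed under-representation probability P(X <= k)
#'
#' @inheritParams hyper_p_over
#' @return P(X <= k).
#' @export
hyper_p_under <- function(N, M, n, k) .hyper_tail(N, M, n, k, upper = FALSE)

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up procedure: with p-values sorted ascending, the adjusted
#' value at position i is min over j >= i of m * p_(j) / j, capped at 1, and
#' returned in the original input order. Adjusted values never fall below the
#' raw ones.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
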