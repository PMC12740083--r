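#' Mean evolutionary age shift of a gene set
#'
#' Difference between the mean stratum rank of the set and the mean rank of
#' the full universe, in units of age categories. Ranks run from 1 (most
#' ancient) to 19 (youngest), so a negative shift means the set skews toward
#' evolutionarily older genes. The baseline is the whole universe, not
#' universe-minus-set, matching the expected-fraction definition M/N used by
#' the enrichment test.
#'
#' @param set_ranks Integer vector of stratum ranks (1..19), one per gene.
#' @param universe A [universe_distribution()].
#' @return Signed mean shift in age categories, in [-18, 18].
#' @export
mean_age_shift <- function(set_ranks, universe) {
  if (length(set_ranks) == 0L) stop("set_ranks must be nonempty")
  mean(set_ranks) - universe_mean_rank(universe)
}

#' Mann-Whitney rank test on ordinal age categories
#'
#' Compares the distribution of a gene set's stratum ranks against a baseline
#' rank multiset. With only 19 distinct values, ties dominate: pooled
#' observations get midranks, and the reported U statistic is the rank-sum
#' statistic of the first sample, U1 = R1 - n1(n1+1)/2.
#'
#' When `n1 * n2 <= exact_limit` the null distribution of the rank sum under
#' exchangeability, conditional on the observed tie pattern, is computed
#' exactly by convolution (a subset-sum count over the pooled midranks) and
#' the two-sided p-value is twice the smaller tail, capped at 1. Otherwise a
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. Degenerate pools with a single distinct value give
#' p = 1 by convention.
#'
#' @param set_ranks Numeric vector, first sample (the gene set).
#' @param baseline_ranks Numeric vector, second sample (the universe).
#' @param exact_limit Use the exact convolution when `n1 * n2` is at or below
#'   this bound (default 200).
#' @return List with `u` (U1), `p` (two-sided p-value), `log10_p` (its
#'   base-10 logarithm, computed in log space so extreme shifts stay
#'   representable) and `method` ("exact" or "normal").
#' @export
mann_whitney_ordinal <- function(set_ranks, baseline_ranks, exact_limit = 200) {
  x <- as.numeric(set_ranks); y <- as.numeric(baseline_ranks)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(u = U1, p = 1, log10_p = 0, method = "degenerate"))
  }
  if (n1 * n2 <= exact_limit) {
    p <- .mw_exact_p(r, n1)
    list(u = U1, p = p, log10_p = log10(p), method = "exact")
  } else {
    lp <- .mw_normal_logp(U1, n1, n2, pooled)
    list(u = U1, p = max(exp(lp), .Machine$double.xmin),
         log10_p = lp / log(10), method = "normal")
  }
}

# exact two-sided p by convolution over the tie pattern: counts subsets of
# size n1 of the pooled midranks by (doubled, so integer) rank sum
.mw_exact_p <- function(midranks, n1) {
  d <- as.integer(round(2 * midranks))  # midranks are multiples of 1/2
  ntot <- length(d)
  w_obs <- sum(d[seq_len(n1)])
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  # f[j+1, s+1] = number of size-j subsets with doubled rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (v in d) {
    jmax <- n1
    for (j in jmax:1L) {
      src <- f[j, ]
      if (any(src != 0)) {
        shifted <- c(rep(0, v), src)[seq_len(smax + 1L)]
        f[j + 1L, ] <- f[j + 1L, ] + shifted
      }
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  sums <- 0:smax
  p_low <- sum(counts[sums <= w_obs]) / total
  p_high <- sum(counts[sums >= w_obs]) / total
  min(1, 2 * min(p_low, p_high))
}

# normal approximation with tie-corrected variance and continuity
# correction; returns log(p) so extreme statistics do not underflow
.mw_normal_logp <- function(U1, n1, n2, pooled) {
  ntot <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (ntot * (ntot - 1))
  v <- n1 * n2 / 12 * ((ntot + 1) - tie_term)
  if (v <= 0) return(0)
  z <- (abs(U1 - n1 * n2 / 2) - 0.5) / sqrt(v)
  z <- max(z, 0)
  min(0, log(2) + stats::pnorm(-z, log.p = TRUE))
}

#' Significance label for a p-value
#'
#' "***" below 0.001, "**" below 0.01, "*" below 0.05, otherwise "ns".
#'
#' @param p A probability in [0, 1].
#' @return One of "***", "**", "*", "ns".
#' @export
significance_label <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Age-shift summary for a DEG set
#'
#' Bundles the mean evolutionary age shift with the Mann-Whitney comparison
#' of the set's stratum ranks against the whole universe's rank multiset.
#'
#' @param set An intersected `deg_set`.
#' @param universe A [universe_distribution()].
#' @param exact_limit Passed to [mann_whitney_ordinal()].
#' @return An `age_shift_result` list: `dataset`, `mean_shift`,
#'   `u_statistic`, `p_value`, `log10_p`, `significance`, `n_set`,
#'   `n_universe`.
#' @export
age_shift_result <- function(set, universe, exact_limit = 200) {
  ranks <- deg_ranks(set)
  if (length(ranks) == 0L) stop("DEG set '", set$name, "' is empty")
  mw <- mann_whitney_ordinal(ranks, universe_ranks(universe),
                             exact_limit = exact_limit)
  structure(list(
    dataset = set$name,
    mean_shift = mean_age_shift(ranks, universe),
    u_statistic = mw$u,
    p_value = mw$p,
    log10_p = mw$log10_p,
    significance = significance_label(mw$p),
    n_set = length(ranks),
    n_universe = attr(universe, "N")
  ), class = "age_shift_result")
}

#' Write age-shift results as a summary table
#'
#' One row per dataset with the Mann-Whitney p-value, significance label and
#' mean age shift in evolutionary age categories (negative = older).
#'
#' @param results A list of `age_shift_result` objects.
#' @param path Output TSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_age_shift_table <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(dataset = r$dataset,
               mann_whitney_p = r$p_value,
               significance = r$significance,
               mean_age_shift = r$mean_shift,
               n_set = r$n_set,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @export
print.age_shift_result <- function(x, ...) {
  cat(sprintf("Age shift for '%s': %.3f categories (n = %d)\n",
              x$dataset, x$mean_shift, x$n_set))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g [%s]\n",
              x$u_statistic, x$p_value, x$significance))
  invisible(x)
}
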