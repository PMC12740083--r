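#' Per-stratum hypergeometric enrichment of a DEG set
#'
#' For each of the 19 strata, tests whether the DEG set contains more (or
#' fewer) genes of that stratum than expected from the universe composition:
#' with N universe genes, M of them in the stratum, and n DEG genes of which
#' k fall in the stratum, the over-representation p-value is P(X >= k) and
#' the under-representation p-value is P(X <= k) under the hypergeometric
#' null. Benjamini-Hochberg correction is applied separately to the 19
#' over-tail and the 19 under-tail p-values of the dataset; strata with
#' M = 0 are kept in the table (p = 1 both tails) but excluded from the
#' correction family, since an untestable stratum should not dilute it.
#'
#' A stratum is flagged "over" when its adjusted over-tail value falls below
#' `alpha`, "under" for the under tail; if both pass, the smaller adjusted
#' value wins (ties go to "over").
#'
#' @param universe A [universe_distribution()].
#' @param set An intersected `deg_set` (see [intersect_with_universe()]).
#' @param scale A [strata_scale()].
#' @param alpha Significance threshold on the adjusted values (default 0.05).
#' @param scope Direction scope label, one of "combined", "up", "down".
#' @return An `enrichment_table`: data frame with one row per stratum in rank
#'   order and columns `rank`, `name`, `N`, `M`, `n`, `k`,
#'   `expected_fraction`, `observed_fraction`, `p_over`, `p_under`, `q_over`,
#'   `q_under`, `flag`; attributes `dataset`, `scope`, `alpha`.
#' @export
stratum_enrichment <- function(universe, set, scale = strata_scale(),
                               alpha = 0.05, scope = "combined") {
  stopifnot(inherits(universe, "universe_distribution"),
            inherits(set, "deg_set"))
  if (is.null(set$genes)) stop("set must be intersected with the universe first")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- set$n
  if (n == 0L) stop("DEG set '", set$name, "' has no genes in the universe")
  N <- attr(universe, "N")
  M <- universe$M
  k <- tabulate(deg_ranks(set), nbins = 19L)
  p_over <- vapply(1:19, function(s) hyper_p_over(N, M[s], n, k[s]), numeric(1))
  p_under <- vapply(1:19, function(s) hyper_p_under(N, M[s], n, k[s]), numeric(1))
  testable <- M > 0L
  q_over <- q_under <- rep(NA_real_, 19L)
  q_over[testable] <- bh_fdr(p_over[testable])
  q_under[testable] <- bh_fdr(p_under[testable])
  flag <- rep("none", 19L)
  sig_o <- testable & q_over < alpha
  sig_u <- testable & q_under < alpha
  flag[sig_o] <- "over"
  flag[sig_u & !sig_o] <- "under"
  both <- sig_o & sig_u
  flag[both] <- ifelse(q_under[both] < q_over[both], "under", "over")
  out <- data.frame(
    rank = scale$rank, name = scale$name, N = N, M = M, n = n, k = k,
    expected_fraction = universe$fraction, observed_fraction = k / n,
    p_over = p_over, p_under = p_under, q_over = q_over, q_under = q_under,
    flag = flag, stringsAsFactors = FALSE
  )
  attr(out, "dataset") <- set$name
  attr(out, "scope") <- scope
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Serialize an enrichment table
#'
#' TSV with one row per stratum and the columns of the table; metadata
#' (dataset, scope, alpha) is written as `#`-prefixed header lines so the
#' file round-trips through [read_enrichment_table()].
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dataset: ", attr(table, "dataset")),
    paste0("# scope: ", attr(table, "scope")),
    paste0("# alpha: ", format(attr(table, "alpha"), digits = 17))
  ), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a serialized enrichment table
#'
#' @param path Path written by [write_enrichment_table()].
#' @return An `enrichment_table`.
#' @export
read_enrichment_table <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- sub("^# [a-z]+: ", "", hdr)
  out <- utils::read.table(path, header = TRUE, sep = "\t", skip = 3L,
                           stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "dataset") <- meta[1]
  attr(out, "scope") <- meta[2]
  attr(out, "alpha") <- as.numeric(meta[3])
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Enrichment table as JSON
#'
#' @param table An `enrichment_table`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
enrichment_to_json <- function(table, path = NULL) {
  obj <- list(dataset = attr(table, "dataset"), scope = attr(table, "scope"),
              alpha = attr(table, "alpha"),
              strata = as.data.frame(table, stringsAsFactors = FALSE))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
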