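#' Direction balance of a dataset across strata
#'
#' For each stratum, the fraction of the dataset's DEGs there that are
#' upregulated: balance = n_up / (n_up + n_down). Genes carrying both
#' directions count once in each. A stratum with no DEGs in either direction
#' has undefined balance (NA).
#'
#' @param table_up,table_down `enrichment_table`s of the up and down views of
#'   the same dataset (see [partition_by_direction()]).
#' @return Data frame with `rank`, `name`, `n_up`, `n_down`, `balance`, plus
#'   a `dataset` attribute.
#' @export
direction_balance <- function(table_up, table_down) {
  stopifnot(inherits(table_up, "enrichment_table"),
            inherits(table_down, "enrichment_table"))
  base_up <- sub("_up$", "", attr(table_up, "dataset"))
  base_dn <- sub("_down$", "", attr(table_down, "dataset"))
  if (!identical(base_up, base_dn)) {
    stop("direction tables belong to different datasets: '", base_up,
         "' vs '", base_dn, "'")
  }
  if (!identical(table_up$rank, table_down$rank)) {
    stop("direction tables cover different strata")
  }
  n_up <- table_up$k; n_down <- table_down$k
  tot <- n_up + n_down
  balance <- ifelse(tot > 0, n_up / tot, NA_real_)
  out <- data.frame(rank = table_up$rank, name = table_up$name,
                    n_up = n_up, n_down = n_down, balance = balance,
                    stringsAsFactors = FALSE)
  attr(out, "dataset") <- base_up
  out
}

#' Cross-dataset dispersion of direction balance
#'
#' Heterogeneity of regulation direction at one stratum, operationalized as
#' the sample standard deviation of the per-dataset balance values. This is a
#' package-defined summary (the underlying claim of rising heterogeneity with
#' evolutionary youth is qualitative); it is invariant under swapping the
#' up/down labels in all datasets at once.
#'
#' @param balances Numeric vector of balance values (one per dataset) at a
#'   chosen stratum; NAs (undefined balances) are dropped.
#' @return Sample standard deviation.
#' @export
cross_dataset_dispersion <- function(balances) {
  b <- balances[!is.na(balances)]
  if (length(b) < 2L) stop("need at least 2 datasets with defined balance")
  stats::sd(b)
}

#' Per-stratum dispersion summary over several datasets
#'
#' @param balance_tables List of data frames from [direction_balance()], one
#'   per dataset.
#' @return Data frame with `rank`, `name`, `n_datasets` (defined balances)
#'   and `dispersion` (NA where fewer than 2 are defined).
#' @export
dispersion_by_stratum <- function(balance_tables) {
  stopifnot(length(balance_tables) >= 1L)
  ranks <- balance_tables[[1]]$rank
  mat <- vapply(balance_tables, function(b) b$balance, numeric(length(ranks)))
  mat <- matrix(mat, nrow = length(ranks))
  n_def <- rowSums(!is.na(mat))
  disp <- rep(NA_real_, length(ranks))
  ok <- n_def >= 2L
  disp[ok] <- apply(mat[ok, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  data.frame(rank = ranks, name = balance_tables[[1]]$name,
             n_datasets = n_def, dispersion = disp, stringsAsFactors = FALSE)
}

#' Serialize balances and their dispersion summary
#'
#' TSV of per-stratum, per-dataset balances with a final dispersion column.
#'
#' @param balance_tables List of [direction_balance()] outputs.
#' @param path Output TSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_balance_table <- function(balance_tables, path) {
  wide <- data.frame(rank = balance_tables[[1]]$rank,
                     name = balance_tables[[1]]$name,
                     stringsAsFactors = FALSE)
  for (b in balance_tables) {
    wide[[attr(b, "dataset")]] <- b$balance
  }
  wide$dispersion <- dispersion_by_stratum(balance_tables)$dispersion
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(wide)
}
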