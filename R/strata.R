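#' The 19-level evolutionary age scale
#'
#' Phylostratigraphy bins genes by the most distant clade in which homologs are
#' detectable. The default scale has 19 ordered strata running from
#' "All living organisms" (rank 1, the most ancient: genes shared with
#' unicellular life) to "Primates" (rank 19, the youngest). Lower rank means
#' older evolutionary origin.
#'
#' @param names Character vector of stratum names in rank order (oldest
#'   first). Defaults to the bundled 19-name scale; a custom scale must still
#'   have exactly 19 unique names so that downstream contracts (one row per
#'   stratum, ranks 1..19) hold.
#' @return A `strata_scale` data frame with columns `rank` (integer 1..19)
#'   and `name`.
#' @examples
#' sc <- strata_scale()
#' sc$name[c(1, 19)]
#' @export
strata_scale <- function(names = NULL) {
  if (is.null(names)) {
    path <- system.file("extdata", "strata19.txt", package = "phylodeg")
    if (nzchar(path)) {
      names <- readLines(path, warn = FALSE)
      names <- names[nzchar(trimws(names))]
    } else {
      names <- .default_strata_names
    }
  }
  names <- trimws(as.character(names))
  if (length(names) != 19L) {
    stop("a strata scale must have exactly 19 strata, got ", length(names))
  }
  if (anyDuplicated(names)) stop("stratum names must be unique")
  out <- data.frame(rank = 1:19, name = names, stringsAsFactors = FALSE)
  class(out) <- c("strata_scale", "data.frame")
  out
}

# fallback used before the package is installed (tests always see the file)
.default_strata_names <- c(
  "All living organisms", "Eukaryota", "Opisthokonta", "Holozoa", "Metazoa",
  "Eumetazoa", "Bilateria", "Deuterostomia", "Chordata", "Olfactores",
  "Craniata", "Euteleostomi", "Tetrapoda", "Amniota", "Mammalia",
  "Boreoeutheria", "Eutheria", "Euarchontoglires", "Primates"
)

#' Normalize gene symbols
#'
#' Uppercases and trims whitespace. No alias resolution is attempted: genes
#' that fail to match the universe are reported as unmapped rather than
#' rescued, keeping the intersection transparent.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

# sep by extension; delimited text only
.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

# resolve a stratum column (names or integer ranks) to ranks; NA = unknown
.resolve_strata <- function(x, scale) {
  x_chr <- trimws(as.character(x))
  rank <- suppressWarnings(as.integer(x_chr))
  is_num <- !is.na(rank) & rank == suppressWarnings(as.numeric(x_chr))
  rank[is_num & (rank < 1L | rank > 19L)] <- NA_integer_
  idx <- match(tolower(x_chr[!is_num]), tolower(scale$name))
  rank[!is_num] <- scale$rank[idx]
  rank
}

#' Load a gene-to-phylostratum age map
#'
#' Reads a delimited table (TSV or CSV by extension) holding one gene symbol
#' and its stratum per row. The stratum column may contain stratum names
#' (matched case-insensitively against the scale) or integer ranks 1..19.
#' Rows with an unknown stratum are rejected and counted; duplicate symbols
#' keep the first occurrence and are counted. Gene symbols are normalized
#' with [normalize_symbols()].
#'
#' @param path Path to the delimited file.
#' @param scale A [strata_scale()].
#' @param col_gene,col_stratum Column names (defaults `"gene"`, `"stratum"`).
#' @param source_label Free-text provenance stored on the result.
#' @return A `gene_age_map` data frame with columns `gene` and `rank`, and
#'   attributes `source_label`, `n_rejected`, `n_duplicates`.
#' @export
load_gene_ages <- function(path, scale = strata_scale(),
                           col_gene = "gene", col_stratum = "stratum",
                           source_label = basename(path)) {
  tab <- .read_delim_auto(path)
  if (!col_gene %in% names(tab) || !col_stratum %in% names(tab)) {
    stop("gene-age table must have columns '", col_gene, "' and '",
         col_stratum, "'; found: ", paste(names(tab), collapse = ", "))
  }
  gene <- normalize_symbols(tab[[col_gene]])
  rank <- .resolve_strata(tab[[col_stratum]], scale)
  bad <- is.na(rank) | !nzchar(gene) | is.na(gene)
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(n_rejected, " row(s) rejected (unknown stratum or empty gene)")
  }
  gene <- gene[!bad]; rank <- rank[!bad]
  dup <- duplicated(gene)
  n_duplicates <- sum(dup)
  if (n_duplicates > 0) {
    warning(n_duplicates, " duplicate gene symbol(s) collapsed, keeping first")
  }
  gene_age_map(gene[!dup], rank[!dup], source_label = source_label,
               n_rejected = n_rejected, n_duplicates = n_duplicates)
}

#' Construct a gene-age map from vectors
#'
#' @param gene Character vector of gene symbols (normalized internally).
#' @param rank Integer stratum ranks in 1..19, parallel to `gene`.
#' @param source_label Provenance string.
#' @param n_rejected,n_duplicates Bookkeeping counts stored as attributes.
#' @return A `gene_age_map` data frame.
#' @export
gene_age_map <- function(gene, rank, source_label = "in-memory",
                         n_rejected = 0L, n_duplicates = 0L) {
  gene <- normalize_symbols(gene)
  rank <- as.integer(rank)
  if (length(gene) != length(rank)) stop("gene and rank lengths differ")
  if (length(gene) == 0L) stop("a gene-age map must contain at least one gene")
  if (anyDuplicated(gene)) stop("gene symbols must be unique after normalization")
  if (any(is.na(rank)) || any(rank < 1L) || any(rank > 19L)) {
    stop("stratum ranks must be integers in 1..19")
  }
  out <- data.frame(gene = gene, rank = rank, stringsAsFactors = FALSE)
  attr(out, "source_label") <- source_label
  attr(out, "n_rejected") <- as.integer(n_rejected)
  attr(out, "n_duplicates") <- as.integer(n_duplicates)
  class(out) <- c("gene_age_map", "data.frame")
  out
}

#' Write a gene-age map in the canonical TSV dialect
#'
#' Columns `gene` and `stratum` (stratum written as its name). Reloading with
#' [load_gene_ages()] round-trips the map exactly.
#'
#' @param map A `gene_age_map`.
#' @param path Output path.
#' @param scale The scale used to spell stratum names.
#' @return `path`, invisibly.
#' @export
write_gene_ages <- function(map, path, scale = strata_scale()) {
  out <- data.frame(gene = map$gene,
                    stratum = scale$name[map$rank],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Baseline distribution of the gene universe over strata
#'
#' The universe is the set of all genes with an age assignment; its
#' per-stratum composition is the baseline every enrichment test is judged
#' against. N is the universe size and M the count of universe genes in a
#' given stratum; strata absent from the map get M = 0.
#'
#' @param map A `gene_age_map`.
#' @param scale A [strata_scale()].
#' @return A `universe_distribution` data frame with columns `rank`, `name`,
#'   `M`, `fraction`, and attribute `N`.
#' @export
universe_distribution <- function(map, scale = strata_scale()) {
  stopifnot(inherits(map, "gene_age_map"))
  M <- tabulate(map$rank, nbins = 19L)
  N <- nrow(map)
  out <- data.frame(rank = scale$rank, name = scale$name, M = M,
                    fraction = M / N, stringsAsFactors = FALSE)
  attr(out, "N") <- N
  class(out) <- c("universe_distribution", "data.frame")
  out
}

#' Mean stratum rank of the universe
#'
#' @param universe A `universe_distribution`.
#' @return Weighted mean rank, sum(rank * M) / N.
#' @export
universe_mean_rank <- function(universe) {
  sum(universe$rank * universe$M) / attr(universe, "N")
}

#' Expand the universe to its rank multiset
#'
#' Each gene contributes its stratum rank once; used as the baseline sample
#' for the Mann-Whitney comparison.
#'
#' @param universe A `universe_distribution`.
#' @return Integer vector of length N.
#' @export
universe_ranks <- function(universe) {
  rep(universe$rank, times = universe$M)
}
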