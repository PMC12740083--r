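#' Read a table of differentially expressed genes
#'
#' Expects delimited text with a gene column and either a direction column
#' (values matched case-insensitively against "up"/"down") or a signed effect
#' column (e.g. a log fold change), or both. When only an effect is present
#' the direction is its sign; zero effects carry no direction and are dropped
#' with a count, as are rows whose direction cannot be parsed.
#'
#' @param path Path to a TSV/CSV file.
#' @param name Dataset label attached to the set.
#' @param col_gene,col_direction,col_effect Column names; defaults `"gene"`,
#'   `"direction"`, `"logfc"`. Direction and effect columns are each optional
#'   but at least one must be present.
#' @return A `deg_set` (pre-intersection): list with `name`, `records`
#'   (data frame of `gene`, `direction`, `effect`) and `n_dropped`.
#' @export
read_deg_table <- function(path, name = basename(path), col_gene = "gene",
                           col_direction = "direction", col_effect = "logfc") {
  tab <- tryCatch(.read_delim_auto(path), error = function(e) {
    stop("could not read DEG table '", path, "': ", conditionMessage(e))
  })
  if (!col_gene %in% names(tab)) {
    stop("DEG table must have a gene column '", col_gene, "'")
  }
  has_dir <- col_direction %in% names(tab)
  has_eff <- col_effect %in% names(tab)
  if (!has_dir && !has_eff) {
    stop("DEG table needs a direction column '", col_direction,
         "' or an effect column '", col_effect, "'")
  }
  gene <- normalize_symbols(tab[[col_gene]])
  effect <- if (has_eff) suppressWarnings(as.numeric(tab[[col_effect]])) else
    rep(NA_real_, length(gene))
  if (has_dir) {
    dir_raw <- tolower(trimws(as.character(tab[[col_direction]])))
    direction <- ifelse(dir_raw %in% c("up", "upregulated"), "up",
                 ifelse(dir_raw %in% c("down", "downregulated"), "down",
                        NA_character_))
  } else {
    direction <- ifelse(is.na(effect) | effect == 0, NA_character_,
                        ifelse(effect > 0, "up", "down"))
  }
  bad <- is.na(direction) | !nzchar(gene)
  n_dropped <- sum(bad)
  if (nrow(tab) == 0L || all(bad)) {
    stop("DEG table '", path, "' has no usable rows")
  }
  records <- data.frame(gene = gene[!bad], direction = direction[!bad],
                        effect = effect[!bad], stringsAsFactors = FALSE)
  structure(list(name = name, records = records,
                 n_dropped = as.integer(n_dropped)),
            class = "deg_set")
}

#' Construct a DEG set from vectors
#'
#' @param gene Character vector of gene symbols.
#' @param direction Character vector, "up"/"down", parallel to `gene`.
#' @param effect Optional numeric effect sizes.
#' @param name Dataset label.
#' @return A pre-intersection `deg_set`.
#' @export
deg_set <- function(gene, direction, effect = NA_real_, name = "deg_set") {
  gene <- normalize_symbols(gene)
  direction <- as.character(direction)
  if (!all(direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  records <- data.frame(gene = gene, direction = direction,
                        effect = as.numeric(effect), stringsAsFactors = FALSE)
  structure(list(name = name, records = records, n_dropped = 0L),
            class = "deg_set")
}

#' Intersect a DEG set with the gene universe
#'
#' Only genes with an age assignment take part in the tests; the rest are
#' dropped and counted in `n_unmapped` (the loss is reported, never imputed).
#' A gene recorded both up and down — as happens when pooling cell types — is
#' kept once in the combined set with direction "both"; the per-direction
#' views from [partition_by_direction()] each contain it.
#'
#' @param set A `deg_set`.
#' @param map A `gene_age_map`.
#' @return An intersected `deg_set`: adds `genes` (data frame of unique
#'   `gene`, `direction` in up/down/both, `rank`), `n` (unique retained
#'   genes), and `n_unmapped`. Idempotent.
#' @export
intersect_with_universe <- function(set, map) {
  stopifnot(inherits(set, "deg_set"), inherits(map, "gene_age_map"))
  rec <- set$records
  dirs <- vapply(split(rec$direction, rec$gene), function(d) {
    u <- unique(d[d %in% c("up", "down", "both")])
    if ("both" %in% u || length(u) == 2L) "both" else u[1]
  }, character(1))
  genes <- data.frame(gene = names(dirs), direction = unname(dirs),
                      stringsAsFactors = FALSE)
  idx <- match(genes$gene, map$gene)
  n_unmapped <- sum(is.na(idx))
  genes <- genes[!is.na(idx), , drop = FALSE]
  genes$rank <- map$rank[idx[!is.na(idx)]]
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  out <- set
  out$genes <- genes
  out$n <- nrow(genes)
  out$n_unmapped <- as.integer(n_unmapped)
  # make re-intersection a no-op on the records side
  out$records <- data.frame(gene = genes$gene, direction = genes$direction,
                            effect = rep(NA_real_, nrow(genes)),
                            stringsAsFactors = FALSE)
  out
}

#' Split an intersected DEG set by direction
#'
#' Genes labeled "both" appear in each partition, so the partition sizes sum
#' to at least `n`, with equality iff there is no conflict.
#'
#' @param set An intersected `deg_set`.
#' @return List with elements `up` and `down`, each an intersected `deg_set`.
#' @export
partition_by_direction <- function(set) {
  stopifnot(inherits(set, "deg_set"))
  if (is.null(set$genes)) stop("set must be intersected with the universe first")
  mk <- function(which) {
    g <- set$genes[set$genes$direction %in% c(which, "both"), , drop = FALSE]
    rownames(g) <- NULL
    out <- set
    out$name <- paste0(set$name, "_", which)
    out$genes <- g
    out$n <- nrow(g)
    out$records <- data.frame(gene = g$gene, direction = rep(which, nrow(g)),
                              effect = rep(NA_real_, nrow(g)),
                              stringsAsFactors = FALSE)
    out
  }
  list(up = mk("up"), down = mk("down"))
}

#' Stratum ranks of an intersected DEG set
#'
#' @param set An intersected `deg_set`.
#' @return Integer vector of ranks, one per unique retained gene.
#' @export
deg_ranks <- function(set) {
  if (is.null(set$genes)) stop("set must be intersected with the universe first")
  set$genes$rank
}
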