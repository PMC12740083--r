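# fixtures are built in code at test time; nothing is stored on disk

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# toy universe: counts per rank (named by rank) -> gene_age_map
toy_map <- function(counts) {
  ranks <- rep(as.integer(names(counts)), times = counts)
  gene_age_map(sprintf("T%04d", seq_along(ranks)), ranks)
}
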