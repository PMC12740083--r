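make_run_fixture <- function(root = tempfile()) {
  dir.create(root, recursive = TRUE)
  cfg1 <- synthetic_config(universe_size = 2000L, n_deg = 150L, beta = 0.6,
                           seed = 41L)
  b1 <- synthetic_bundle(cfg1)
  write_gene_ages(b1$universe, file.path(root, "ages.tsv"))
  utils::write.table(
    data.frame(gene = b1$deg$genes$gene, direction = b1$deg$genes$direction),
    file.path(root, "set1.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg2 <- synthetic_config(universe_size = 2000L, n_deg = 100L, seed = 42L)
  b2 <- list(deg = sample_deg_set(b1$universe, cfg2, seed = 77L))
  utils::write.table(
    data.frame(gene = b2$deg$genes$gene, direction = b2$deg$genes$direction),
    file.path(root, "set2.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    gene_ages = "ages.tsv",
    datasets = list(list(name = "biased", path = "set1.tsv"),
                    list(name = "null", path = "set2.tsv")),
    alpha = 0.05,
    output_dir = file.path(root, "out"),
    figures = FALSE
  ), file.path(root, "run.yaml"))
  root
}

test_that("run_analysis produces tables, summaries and a manifest per dataset", {
  root <- make_run_fixture()
  res <- run_analysis(file.path(root, "run.yaml"))
  expect_named(res$results, c("biased", "null"))
  out <- file.path(root, "out")
  for (ds in c("biased", "null")) {
    for (scope in c("combined", "up", "down")) {
      expect_true(file.exists(file.path(out,
        paste0(ds, "_enrichment_", scope, ".tsv"))))
    }
  }
  expect_true(file.exists(file.path(out, "age_shift.tsv")))
  expect_true(file.exists(file.path(out, "direction_balance.tsv")))
  manifest <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_equal(manifest$datasets$biased$status, "ok")
  expect_equal(manifest$universe_size, 2000L)
  # the biased set must register as ancient-skewed, the null set not strongly
  expect_lt(res$results$biased$age_shift$mean_shift, 0)
  expect_lt(res$results$biased$age_shift$p_value, 0.001)
})

test_that("reruns are deterministic and reloaded tables equal in-memory ones", {
  root <- make_run_fixture()
  res1 <- run_analysis(file.path(root, "run.yaml"))
  first <- readLines(file.path(root, "out", "biased_enrichment_combined.tsv"))
  res2 <- run_analysis(file.path(root, "run.yaml"))
  second <- readLines(file.path(root, "out", "biased_enrichment_combined.tsv"))
  expect_identical(first, second)
  reloaded <- read_enrichment_table(
    file.path(root, "out", "biased_enrichment_combined.tsv"))
  mem <- res2$results$biased$tables$combined
  expect_equal(reloaded$k, mem$k)
  expect_equal(reloaded$p_over, mem$p_over, tolerance = 1e-12)
  expect_equal(reloaded$flag, mem$flag)
})

test_that("a broken dataset fails alone while the rest completes", {
  root <- make_run_fixture()
  cfg <- yaml::read_yaml(file.path(root, "run.yaml"))
  cfg$datasets[[3]] <- list(name = "missing", path = "no_such_file.tsv")
  yaml::write_yaml(cfg, file.path(root, "run.yaml"))
  expect_message(res <- run_analysis(file.path(root, "run.yaml")), "failed")
  expect_named(res$results, c("biased", "null"))
  manifest <- jsonlite::fromJSON(file.path(root, "out", "manifest.json"))
  expect_equal(manifest$datasets$missing$status, "failed")
})

test_that("config validation rejects malformed runs", {
  root <- tempfile(); dir.create(root)
  yaml::write_yaml(list(datasets = list(list(name = "a", path = "x"))),
                   file.path(root, "bad.yaml"))
  expect_error(read_run_config(file.path(root, "bad.yaml")), "gene_ages")
  yaml::write_yaml(list(gene_ages = "g.tsv", alpha = 0.5,
                        datasets = list(list(name = "a", path = "x"),
                                        list(name = "a", path = "y"))),
                   file.path(root, "dup.yaml"))
  expect_error(read_run_config(file.path(root, "dup.yaml")), "unique")
})

test_that("bar charts carry the three series and the flagged stars", {
  cfg <- synthetic_config(universe_size = 2000L, n_deg = 200L, beta = 1,
                          seed = 51L)
  b <- synthetic_bundle(cfg)
  uni <- universe_distribution(b$universe)
  parts <- partition_by_direction(b$deg)
  tu <- stratum_enrichment(uni, parts$up, scope = "up")
  td <- stratum_enrichment(uni, parts$down, scope = "down")
  comb <- stratum_enrichment(uni, b$deg)
  gg <- render_barchart(tu, td, uni, flags = comb$flag, title = "synthetic")
  expect_s3_class(gg, "ggplot")
  built <- ggplot2::ggplot_build(gg)
  expect_equal(nrow(built$data[[1]]), 3 * 19)  # three bars per stratum
  n_stars <- sum(comb$flag != "none")
  expect_gt(n_stars, 0)  # strong bias must flag something
  expect_equal(nrow(built$data[[2]]), n_stars)

  # an empty down partition still renders
  up_only <- intersect_with_universe(
    deg_set(b$universe$gene[1:50], rep("up", 50)), b$universe)
  pu <- partition_by_direction(up_only)
  tu2 <- stratum_enrichment(uni, pu$up, scope = "up")
  expect_error(stratum_enrichment(uni, pu$down, scope = "down"), "no genes")
  # down table with zero counts built from the up table shape
  td2 <- tu2; td2$k <- 0L; td2$n <- 0L
  gg2 <- render_barchart(tu2, td2, uni)
  expect_s3_class(gg2, "ggplot")
})
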