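test_that("config validation catches degenerate settings", {
  expect_error(synthetic_config(composition = rep(0, 19)), "degenerate")
  expect_error(synthetic_config(composition = rep(0.1, 19)), "sum to 1")
  expect_error(synthetic_config(composition = rep(1 / 5, 5)), "19")
  expect_error(synthetic_config(beta = -1), "beta")
  expect_error(synthetic_config(n_deg = 100, universe_size = 50), "n_deg")
  expect_lt(abs(sum(default_composition()) - 1), 1e-12)
})

test_that("universe sampling is seeded, reproducible and composition-faithful", {
  one_hot <- c(1, rep(0, 18))
  cfg1 <- synthetic_config(universe_size = 200L, composition = one_hot,
                           n_deg = 50L, seed = 4L)
  expect_true(all(sample_universe(cfg1)$rank == 1L))

  cfg2 <- synthetic_config(universe_size = 19000L,
                           composition = rep(1 / 19, 19), seed = 0L)
  uni <- sample_universe(cfg2)
  counts <- tabulate(uni$rank, 19)
  sd_mult <- sqrt(19000 * (1 / 19) * (18 / 19))
  expect_true(all(abs(counts - 1000) <= 5 * sd_mult))

  expect_identical(sample_universe(cfg2), sample_universe(cfg2))
})

test_that("DEG sampling is uniform at beta = 0 and degenerate at extreme beta", {
  cfg <- synthetic_config(universe_size = 2000L, n_deg = 200L, seed = 8L)
  umap <- sample_universe(cfg)
  uni <- universe_distribution(umap)
  # beta = 0: per-stratum means match the hypergeometric expectation
  n_rep <- 500
  acc <- numeric(19)
  set.seed(8)
  for (i in seq_len(n_rep)) {
    dset <- sample_deg_set(umap, cfg, seed = NULL)
    acc <- acc + tabulate(deg_ranks(dset), 19)
  }
  expected <- 200 * uni$M / 2000
  se <- sqrt(200 * (uni$M / 2000) * (1 - uni$M / 2000) *
               (2000 - 200) / (2000 - 1) / n_rep)
  dev <- abs(acc / n_rep - expected)
  expect_true(all(dev[uni$M > 0] <= 3.5 * se[uni$M > 0] + 1e-9))

  # beta -> infinity: only the most ancient genes are drawn
  cfg_inf <- synthetic_config(universe_size = 2000L, n_deg = 100L,
                              beta = 50, seed = 8L)
  dset_inf <- sample_deg_set(umap, cfg_inf, seed = 9L)
  expect_true(all(deg_ranks(dset_inf) == 1L))
  expect_equal(dset_inf$n_unmapped, 0L)
})

test_that("the symmetric direction model yields a balanced up-fraction", {
  # pool 40,000 direction draws so the binomial check has negligible
  # false-alarm probability while still detecting any real asymmetry
  n_up <- 0L
  for (seed in 1:20) {
    cfg <- synthetic_config(universe_size = 5000L, n_deg = 2000L, seed = seed)
    b <- synthetic_bundle(cfg)
    n_up <- n_up + sum(b$deg$genes$direction == "up")
  }
  ci <- stats::binom.test(n_up, 40000, 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("bundles are deterministic and round-trip through their TSV form", {
  cfg <- synthetic_config(universe_size = 800L, n_deg = 120L, beta = 0.4,
                          seed = 33L)
  b1 <- synthetic_bundle(cfg)
  b2 <- synthetic_bundle(cfg)
  expect_identical(b1$universe, b2$universe)
  expect_identical(b1$deg$genes, b2$deg$genes)

  dir <- tempfile()
  write_bundle(b1, dir)
  map_back <- load_gene_ages(file.path(dir, "universe.tsv"))
  deg_back <- intersect_with_universe(
    read_deg_table(file.path(dir, "deg.tsv"), name = "synthetic_deg"),
    map_back)
  expect_equal(nrow(map_back), 800L)
  expect_equal(deg_back$n, 120L)
  expect_equal(deg_back$n_unmapped, 0L)
  expect_setequal(deg_back$genes$gene, b1$deg$genes$gene)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$beta, 0.4)
  expect_equal(truth$seed, 33L)
})

test_that("estimate_beta recovers the null and hits the bound on degenerate sets", {
  cfg <- synthetic_config(n_deg = 5000L, seed = 0L)
  b <- synthetic_bundle(cfg)
  uni <- universe_distribution(b$universe)
  expect_lt(abs(estimate_beta(b$deg, uni)), 0.05)

  # a set of only rank-1 genes is more ancient than any finite beta explains
  all_ancient <- intersect_with_universe(
    deg_set(b$universe$gene[b$universe$rank == 1][1:100], rep("up", 100)),
    b$universe)
  est <- estimate_beta(all_ancient, uni)
  expect_equal(as.numeric(est), 50)
  expect_true(isTRUE(attr(est, "boundary")))

  # sets younger than the universe mean never get a positive shift estimate
  young <- intersect_with_universe(
    deg_set(b$universe$gene[b$universe$rank == 19][1:50], rep("up", 50)),
    b$universe)
  expect_equal(estimate_beta(young, uni), 0)
})

test_that("beta estimates tighten as the DEG set grows", {
  cfg0 <- synthetic_config(seed = 0L)
  umap <- sample_universe(cfg0, seed = 510L)
  uni <- universe_distribution(umap)
  rmse <- vapply(c(200L, 1000L, 5000L), function(n) {
    cfg <- synthetic_config(beta = 0.5, n_deg = n, seed = 0L)
    set.seed(600 + n)
    errs <- vapply(1:30, function(i) {
      est <- estimate_beta(sample_deg_set(umap, cfg, seed = NULL), uni)
      as.numeric(est) - 0.5
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_lt(rmse[3], rmse[1])
  expect_lt(rmse[2], rmse[1])
})
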