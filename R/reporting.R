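#' Read a run configuration
#'
#' YAML with fields: `gene_ages` (path to the age map), `datasets` (list of
#' entries with `name`, `path` and optional column names `col_gene`,
#' `col_direction`, `col_effect`), optional `alpha` (default 0.05),
#' `output_dir` (default "phylodeg_results"), `figures` (default TRUE) and
#' `seed`. Relative paths are resolved against the config file's directory.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  if (is.null(cfg$gene_ages)) stop("config must name a 'gene_ages' file")
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L) {
    stop("config must list at least one dataset")
  }
  cfg$gene_ages <- resolve(cfg$gene_ages)
  cfg$datasets <- lapply(cfg$datasets, function(d) {
    if (is.null(d$name) || is.null(d$path)) {
      stop("each dataset needs 'name' and 'path'")
    }
    d$path <- resolve(d$path)
    d
  })
  nm <- vapply(cfg$datasets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(cfg$output_dir)) cfg$output_dir <- "phylodeg_results"
  cfg$output_dir <- resolve(cfg$output_dir)
  if (is.null(cfg$figures)) cfg$figures <- TRUE
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis for every dataset in a config
#'
#' For each dataset: ingest, intersect with the universe, compute enrichment
#' tables in the combined/up/down scopes, the age-shift summary and the
#' direction balance, and serialize everything under `output_dir`. A dataset
#' that fails ingestion is recorded in the manifest and skipped; the others
#' still complete. Outputs are deterministic for fixed inputs.
#'
#' @param config A `run_config` (or a path to one).
#' @return Invisibly, a list with `results` (per dataset: enrichment tables,
#'   age shift, balance), `age_shift_table`, `dispersion`, `manifest`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  scale <- strata_scale()
  map <- load_gene_ages(config$gene_ages, scale)
  universe <- universe_distribution(map, scale)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  statuses <- list()
  for (d in config$datasets) {
    res <- tryCatch({
      args <- list(path = d$path, name = d$name)
      for (a in c("col_gene", "col_direction", "col_effect")) {
        if (!is.null(d[[a]])) args[[sub("col_", "col_", a)]] <- d[[a]]
      }
      raw <- do.call(read_deg_table, args)
      set <- intersect_with_universe(raw, map)
      parts <- partition_by_direction(set)
      tables <- list(
        combined = stratum_enrichment(universe, set, scale, config$alpha, "combined"),
        up = stratum_enrichment(universe, parts$up, scale, config$alpha, "up"),
        down = stratum_enrichment(universe, parts$down, scale, config$alpha, "down")
      )
      shift <- age_shift_result(set, universe)
      balance <- direction_balance(tables$up, tables$down)
      for (scope in names(tables)) {
        write_enrichment_table(tables[[scope]],
          file.path(out_dir, paste0(d$name, "_enrichment_", scope, ".tsv")))
      }
      if (isTRUE(config$figures)) {
        fig <- render_barchart(tables$up, tables$down, universe,
                               flags = tables$combined$flag,
                               title = d$name)
        ggplot2::ggsave(file.path(out_dir, paste0(d$name, "_strata.pdf")),
                        fig, width = 9, height = 4.5)
      }
      list(set = set, tables = tables, age_shift = shift, balance = balance,
           n_unmapped = set$n_unmapped)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      statuses[[d$name]] <- list(status = "failed",
                                 error = conditionMessage(res))
      message("dataset '", d$name, "' failed: ", conditionMessage(res))
    } else {
      statuses[[d$name]] <- list(status = "ok", n = res$set$n,
                                 n_unmapped = res$n_unmapped)
      results[[d$name]] <- res
    }
  }
  shift_df <- NULL
  dispersion <- NULL
  if (length(results) > 0) {
    shift_df <- write_age_shift_table(lapply(results, `[[`, "age_shift"),
                                      file.path(out_dir, "age_shift.tsv"))
    balances <- lapply(results, `[[`, "balance")
    if (length(balances) >= 1) {
      write_balance_table(balances, file.path(out_dir, "direction_balance.tsv"))
      dispersion <- dispersion_by_stratum(balances)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("phylodeg")),
    gene_ages = config$gene_ages,
    universe_size = attr(universe, "N"),
    alpha = config$alpha,
    datasets = statuses
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, age_shift_table = shift_df,
                 dispersion = dispersion, manifest = manifest,
                 universe = universe))
}

#' Grouped bar chart of a dataset's strata profile
#'
#' Per stratum (in rank order, most ancient leftmost): the percentage of
#' upregulated genes, of downregulated genes, and the expected percentage
#' from the universe (M/N). Percentages are computed within each series so
#' every series sums to 100% across strata; this denominator convention is
#' switchable via `denominator`. Significance stars from the supplied flags
#' are drawn above the strata: one color for over-representation, another
#' for under-representation.
#'
#' @param table_up,table_down `enrichment_table`s of the two direction views.
#' @param universe A [universe_distribution()].
#' @param flags Character vector of length 19 with values in
#'   over/under/none (typically the combined table's `flag` column).
#' @param title Plot title.
#' @param denominator "per_direction" (default; each series sums to 100%) or
#'   "combined" (both direction series divided by the combined n).
#' @return A ggplot object.
#' @export
render_barchart <- function(table_up, table_down, universe,
                            flags = rep("none", 19L), title = NULL,
                            denominator = c("per_direction", "combined")) {
  denominator <- match.arg(denominator)
  stopifnot(identical(table_up$rank, table_down$rank))
  if (denominator == "per_direction") {
    up_pct <- if (table_up$n[1] > 0) 100 * table_up$k / table_up$n[1] else rep(0, 19)
    dn_pct <- if (table_down$n[1] > 0) 100 * table_down$k / table_down$n[1] else rep(0, 19)
  } else {
    ncomb <- max(1, table_up$n[1] + table_down$n[1])
    up_pct <- 100 * table_up$k / ncomb
    dn_pct <- 100 * table_down$k / ncomb
  }
  exp_pct <- 100 * universe$fraction
  df <- data.frame(
    stratum = factor(rep(universe$name, 3), levels = universe$name),
    series = rep(c("Upregulated", "Downregulated", "Expected"), each = 19),
    pct = c(up_pct, dn_pct, exp_pct)
  )
  stars <- data.frame(stratum = factor(universe$name, levels = universe$name),
                      flag = flags,
                      y = apply(cbind(up_pct, dn_pct, exp_pct), 1, max) + 1.5)
  stars <- stars[stars$flag != "none", , drop = FALSE]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$pct,
                                         fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(Upregulated = "#3b6fb6",
                                          Downregulated = "#e08214",
                                          Expected = "#4daf4a")) +
    ggplot2::labs(x = "Evolutionary age stratum (ancient to recent)",
                  y = "Percentage of genes", fill = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (nrow(stars) > 0) {
    gg <- gg + ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$stratum, y = .data$y, label = "*",
                   color = .data$flag),
      inherit.aes = FALSE, size = 6, show.legend = FALSE) +
      ggplot2::scale_color_manual(values = c(over = "red", under = "black"))
  }
  gg
}

#' Null-calibration and power simulation report
#'
#' Draws `n_rep` synthetic DEG sets at each requested beta from one synthetic
#' universe and summarises per-stratum rejection rates of the raw one-tailed
#' p-values at `alpha`, plus the distribution of mean age shifts. Used to
#' check type-I calibration (beta = 0) and to gauge power at a given shift.
#'
#' @param config A [synthetic_config()]; its `beta` is overridden by `betas`.
#' @param betas Numeric vector of shift parameters to simulate.
#' @param n_rep Replicates per beta.
#' @param alpha Rejection threshold on the raw p-values.
#' @return Data frame with one row per (beta, stratum): rejection rates for
#'   both tails and the mean over replicates of the mean age shift.
#' @export
calibrate_null <- function(config, betas = 0, n_rep = 200, alpha = 0.05) {
  set.seed(config$seed)
  universe_map <- sample_universe(config, seed = NULL)
  universe <- universe_distribution(universe_map)
  out <- list()
  for (b in betas) {
    cfg_b <- config; cfg_b$beta <- b
    rej_over <- rej_under <- numeric(19)
    shifts <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      dset <- sample_deg_set(universe_map, cfg_b, seed = NULL)
      tab <- stratum_enrichment(universe, dset, alpha = alpha)
      rej_over <- rej_over + (tab$p_over < alpha)
      rej_under <- rej_under + (tab$p_under < alpha)
      shifts[i] <- mean_age_shift(deg_ranks(dset), universe)
    }
    out[[length(out) + 1L]] <- data.frame(
      beta = b, rank = 1:19,
      reject_over = rej_over / n_rep, reject_under = rej_under / n_rep,
      mean_shift = mean(shifts), se_shift = stats::sd(shifts) / sqrt(n_rep)
    )
  }
  do.call(rbind, out)
}
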