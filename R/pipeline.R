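# End-to-end orchestration: simulate (or load) -> diversity -> ordination
# -> network -> domain importance, writing every result as TSV plus a log
# and a manifest that suffices to reproduce the run. Each stochastic stage
# derives its own seed deterministically from the global seed and the
# stage name, so stages never share or perturb each other's streams.

#' Default pipeline configuration
#'
#' Simulation mode with the package's study-condition defaults: 14 sites
#' across 1,936-3,896 m, three domains at their standard depths, the
#' positive-dominated archaea-hub planted structure, Spearman correlation
#' with |r| > 0.6 and p < 0.01 edges, Hellinger ordination, an
#' elevation-vs-soil variance partition, and a 5-point random-removal
#' robustness grid with 100 reps.
#'
#' @param seed global integer seed.
#' @return a named list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = TRUE,
    counts_path = NULL, taxonomy_path = NULL, metadata_path = NULL,
    depths = c(bacteria = 30671, archaea = 17561, eukaryota = 42299),
    correlation_method = "spearman",
    min_rel_abund = 0.0005,
    r_threshold = 0.6, p_threshold = 0.01,
    transform = "hellinger",
    rda_variables = c("elevation", "longitude", "MAT", "MAP", "pH",
                      "TN", "TC", "TC_TN", "EC"),
    vpa_groups = list(elevation = "elevation",
                      soil = c("pH", "EC", "TC", "TN", "TC_TN")),
    robustness_fractions = seq(0, 0.8, by = 0.2),
    robustness_reps = 100
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unset keys fall back to [default_run_config()] values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (!is.null(cfg$depths)) cfg$depths <- unlist(cfg$depths)
  if (!is.null(cfg$vpa_groups)) cfg$vpa_groups <- lapply(cfg$vpa_groups, unlist)
  cfg
}

validate_config <- function(config) {
  if (isTRUE(config$simulate)) return(invisible(config))
  need <- c("counts_path", "taxonomy_path", "metadata_path")
  missing <- need[vapply(need, function(k) is.null(config[[k]]), TRUE)]
  if (length(missing)) {
    stop("config has no simulation block and is missing input path(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, per-domain diversity and regressions, PCA / RDA
#' / VPA per domain, rare-OTU filtering and network construction, topology,
#' ablation correlation frequencies and robustness, writing all outputs
#' under `out_dir` together with `run.log` and `manifest.json`. Re-running
#' with the same configuration reproduces the outputs byte for byte.
#'
#' @param config configuration list (see [default_run_config()]).
#' @param out_dir output directory.
#' @param overwrite overwrite a directory that already contains a manifest
#'   (default FALSE: such a directory is an error).
#' @return invisibly, `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         overwrite = FALSE) {
  validate_config(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output directory already holds a run (", manifest_path,
         "); use overwrite = TRUE to replace it")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(NULL, file = log_path)
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  }
  seed <- config$seed %||% 1L

  if (isTRUE(config$simulate)) {
    log_line("simulate", sprintf("generating synthetic data (seed %d)", seed))
    gcfg <- gradient_config(seed = stage_seed(seed, "metadata"))
    metadata <- generate_metadata(gcfg)
    sim <- generate_otu_tables(metadata, default_domain_configs(),
                               default_planted_structure(),
                               seed = stage_seed(seed, "otu_tables"))
    table <- sim$table
    write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
    write_otu_table(table, file.path(out_dir, "otu.tsv"),
                    file.path(out_dir, "taxonomy.tsv"))
    write_ground_truth(sim$truth, file.path(out_dir, "truth_edges.tsv"),
                       file.path(out_dir, "truth_params.txt"))
  } else {
    log_line("load", config$counts_path)
    table <- read_otu_table(config$counts_path, config$taxonomy_path)
    metadata <- read_metadata(config$metadata_path)
  }

  log_line("diversity", "rarefying and computing alpha-diversity")
  div <- diversity_table(table, config$depths,
                         seed = stage_seed(seed, "rarefy"))
  write_tsv(div, file.path(out_dir, "diversity.tsv"))
  reg <- regression_table(div, metadata)
  write_tsv(reg, file.path(out_dir, "regressions.tsv"))

  log_line("ordination", "PCA / RDA / VPA per domain")
  ord_rows <- list()
  vpa_rows <- list()
  for (d in intersect(DOMAINS, unique(table$domain))) {
    pcares <- community_pca(table, transform = config$transform, domain = d)
    rdares <- community_rda(table, metadata, config$rda_variables,
                            transform = config$transform, domain = d)
    vpares <- variation_partition(table, metadata, config$vpa_groups,
                                  transform = config$transform, domain = d)
    ord_rows[[d]] <- data.frame(
      domain = d,
      pc1 = 100 * pcares$variance_explained[1],
      pc2 = 100 * pcares$variance_explained[2],
      rda1 = 100 * rdares$variance_explained[1],
      rda2 = 100 * ifelse(length(rdares$variance_explained) > 1,
                          rdares$variance_explained[2], NA_real_),
      constrained = 100 * rdares$constrained_fraction,
      stringsAsFactors = FALSE)
    vpa_rows[[d]] <- data.frame(
      domain = d,
      component = c(names(vpares$group_fractions),
                    names(vpares$individual_fractions),
                    "shared", "residual"),
      kind = c(rep("group", length(vpares$group_fractions)),
               rep("individual", length(vpares$individual_fractions)),
               "shared", "residual"),
      fraction = c(unname(vpares$group_fractions),
                   unname(vpares$individual_fractions),
                   vpares$shared_fraction, vpares$residual_fraction),
      stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, c(ord_rows, list(make.row.names = FALSE))),
            file.path(out_dir, "ordination.tsv"))
  write_tsv(do.call(rbind, c(vpa_rows, list(make.row.names = FALSE))),
            file.path(out_dir, "vpa.tsv"))

  log_line("network", sprintf("filtering (> %g) and %s correlation",
                              config$min_rel_abund, config$correlation_method))
  filtered <- filter_rare_otus(table, config$min_rel_abund)
  corr <- if (config$correlation_method == "sparcc") {
    sparcc_matrix(filtered, seed = stage_seed(seed, "sparcc"))
  } else {
    spearman_matrix(filtered)
  }
  write_correlation(corr, file.path(out_dir, "correlation"))
  net <- build_network(corr, filtered$domain,
                       pooled_rel_abundance(filtered),
                       r_threshold = config$r_threshold,
                       p_threshold = config$p_threshold)
  write_network(net, file.path(out_dir, "edges.tsv"), "edge_tsv")
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  topo <- network_topology(net)
  write_tsv(topo, file.path(out_dir, "topology.tsv"))

  log_line("importance", "ablation frequencies and robustness")
  freq <- ablation_frequencies(net)
  write_tsv(freq, file.path(out_dir, "frequencies.tsv"))
  rob <- ablation_robustness(net, fractions = config$robustness_fractions,
                             n_reps = config$robustness_reps,
                             seed = stage_seed(seed, "robustness"))
  curve_rows <- do.call(rbind, lapply(rob$curves, function(cu) {
    data.frame(scenario = cu$scenario, cu$summary, stringsAsFactors = FALSE)
  }))
  rownames(curve_rows) <- NULL
  write_tsv(curve_rows, file.path(out_dir, "robustness.tsv"))
  write_tsv(rob$comparisons, file.path(out_dir, "robustness_comparisons.tsv"))

  config_out <- config
  config_out$depths <- as.list(config$depths)
  manifest <- list(
    package = "elevnet",
    version = as.character(utils::packageVersion("elevnet")),
    config = config_out,
    stage_seeds = list(metadata = stage_seed(seed, "metadata"),
                       otu_tables = stage_seed(seed, "otu_tables"),
                       rarefy = stage_seed(seed, "rarefy"),
                       robustness = stage_seed(seed, "robustness"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  log_line("done", "all stages complete")
  invisible(out_dir)
}
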