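#' Run the full synthetic-study pipeline
#'
#' Orchestrates every stage on generated data: simulate (genome, gene
#' models, methylome with planted depth-responsive DMCs, 18 bisulfite count
#' tables, expression, GO map, shell images) -> methylation calling ->
#' methylome characterization -> the nine differential comparisons ->
#' effect disentangling -> GO enrichment of depth-only differentially
#' methylated genes -> color phenotyping. Each stage writes TSV/BED/Newick
#' outputs under `out_dir`, and a JSON log records parameters, seed and the
#' config digest. Reruns with the same configuration and seed produce
#' byte-identical tables.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param min_coverage Minimum per-site coverage for calling (default 10).
#' @param diff_threshold,q_threshold DMC filter thresholds (defaults 25
#'   points, 0.05).
#' @param darkness_shift Darkness increase applied to the treatment groups'
#'   images at the affected times.
#' @return Invisibly, a list with the main in-memory results: `design`,
#'   `summary` (global methylation), `classes` (gene classification),
#'   `effects`, `enrichment`, `phenotype`, and `paths` of written files.
#' @export
run_pipeline <- function(config, out_dir,
                         min_coverage = 10,
                         diff_threshold = 25, q_threshold = 0.05,
                         darkness_shift = 0.3) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  log <- list(seed = config$seed,
              parameters = list(min_coverage = min_coverage,
                                diff_threshold = diff_threshold,
                                q_threshold = q_threshold,
                                darkness_shift = darkness_shift),
              config = unclass(config))

  # --- simulate ----------------------------------------------------------
  genome <- generate_genome(config)
  genes <- generate_gene_models(genome, config)
  methylome <- assign_methylome(genome, genes, config)
  methylome <- plant_dmcs(methylome,
                          n_sites = config$n_planted_dmcs,
                          delta_points = config$planted_effect_size,
                          affected_group = "T",
                          affected_times = c("S2", "S3"),
                          seed = config$seed + 3L)
  design <- sample_design(config$n_genotypes, config$treatments,
                          config$n_times)
  reports <- simulate_counts(methylome, design, config)
  classes_true <- attr(methylome, "gene_classes")
  expression <- simulate_expression(genes, classes_true, coupling = "hump",
                                    seed = config$seed + 5L)
  go_map <- simulate_go_map(genes, seed = config$seed + 6L)

  paths$genome <- write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
  paths$genes <- write_gene_models_gff3(genes, file.path(out_dir, "genes.gff3"))
  paths$design <- write_sample_design(design, file.path(out_dir, "design.tsv"))
  paths$truth <- write_planted_truth(methylome,
                                     file.path(out_dir, "planted_truth.tsv"))

  # --- call --------------------------------------------------------------
  calls <- call_methylation(reports, min_coverage = min_coverage)
  summary <- global_methylation_summary(calls)
  paths$summary <- file.path(out_dir, "global_methylation.tsv")
  readr::write_tsv(summary, paths$summary, progress = FALSE)

  # --- characterize ------------------------------------------------------
  cpg_calls <- dplyr::filter(calls, .data$context == "CpG")
  profile <- metagene_profile(cpg_calls, genes, flank = config$flank)
  gbmr <- gene_body_methylation(cpg_calls, genes)
  classes <- classify_genes_by_rank(gbmr)
  meth_expr <- methylation_by_expression_rank(classes, expression)
  paths$profile <- file.path(out_dir, "metagene_profile.tsv")
  readr::write_tsv(profile, paths$profile, progress = FALSE)
  paths$classes <- file.path(out_dir, "gene_methylation.tsv")
  readr::write_tsv(classes, paths$classes, progress = FALSE)
  paths$meth_expr <- file.path(out_dir, "methylation_by_expression.tsv")
  readr::write_tsv(meth_expr, paths$meth_expr, progress = FALSE)

  united_all <- unite_positions(cpg_calls, context_filter = "CpG")
  dendro <- cluster_samples(united_all)
  paths$dendrogram <- file.path(out_dir, "sample_clustering.nwk")
  cluster_newick(dendro, paths$dendrogram)

  # --- diff + effects ----------------------------------------------------
  comp <- run_comparisons(calls, design, context = "CpG",
                          diff_threshold = diff_threshold,
                          q_threshold = q_threshold)
  paths$effects <- write_effect_report(comp$effects,
                                       file.path(out_dir, "effect_report.tsv"))
  for (nm in names(comp$dmc_sets)) {
    p <- file.path(out_dir, paste0("dmc_", gsub("[^A-Za-z0-9]+", "_", nm),
                                   ".bed"))
    write_dmc_bed(comp$dmc_sets[[nm]], p)
  }

  # --- enrich ------------------------------------------------------------
  dm_genes <- map_dmcs_to_genes(comp$effects$depth_only, genes)
  enrichment <- NULL
  if (nrow(dm_genes) > 0) {
    study <- intersect(dm_genes$gene_id, unique(go_map$gene_id))
    if (length(study) > 0) {
      enrichment <- go_enrichment(study, unique(go_map$gene_id), go_map)
      paths$enrichment <- file.path(out_dir, "go_enrichment.tsv")
      readr::write_tsv(enrichment, paths$enrichment, progress = FALSE)
    }
  }

  # --- color -------------------------------------------------------------
  shifted_times <- c("S2", "S3")
  groups <- list()
  for (tr in config$treatments) {
    for (ti in sprintf("S%d", seq_len(config$n_times))) {
      shift <- if (tr == "T" && ti %in% shifted_times) darkness_shift else 0
      groups[[paste0(tr, "-", ti)]] <- generate_shell_images(
        10, darkness_shift = shift,
        seed = config$seed + 7L + length(groups))
    }
  }
  phenotype <- phenotype_pipeline(groups)
  paths <- c(paths, as.list(write_phenotype_tables(phenotype, out_dir)))

  log$config_digest <- config_digest(config)
  paths$log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(design = design, summary = summary, classes = classes,
                 profile = profile, effects = comp$effects,
                 dmc_sets = comp$dmc_sets, enrichment = enrichment,
                 phenotype = phenotype, paths = paths))
}

# stable digest of a configuration (md5 of its canonical JSON serialization)
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
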