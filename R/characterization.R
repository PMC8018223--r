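#' Metagene methylation profile (scaled gene bodies with fixed flanks)
#'
#' deepTools-style scale-regions profile: each gene body is rescaled to
#' `body_bins` bins, with `flank` bp upstream of the TSS and downstream of
#' the TES cut into fixed `flank_bin_bp` bins. Coordinates are strand-aware:
#' minus-strand genes are reversed so bin 1 is always the far upstream end.
#' Site fractions are averaged within each gene's bins first, then across
#' genes, so long genes do not dominate.
#'
#' @param calls A `methylation_calls` tibble; sites are averaged across
#'   samples if several are present. Restrict to a context first if desired
#'   (the study profiles CpG methylation).
#' @param gene_set A `gene_set` tibble.
#' @param flank Flank size in bp (default 3000).
#' @param body_bins Number of bins the gene body is scaled to.
#' @param flank_bin_bp Width of each flank bin in bp.
#' @return A tibble (class `metagene_profile`) with `bin`, `region`
#'   (`upstream`/`body`/`downstream`), `mean_fraction`, `n_sites`,
#'   `n_genes`.
#' @export
metagene_profile <- function(calls, gene_set, flank = 3000, body_bins = 60,
                             flank_bin_bp = 100) {
  n_flank_bins <- as.integer(ceiling(flank / flank_bin_bp))
  site <- calls |>
    group_by(.data$scaffold, .data$position) |>
    summarise(fraction = mean(.data$fraction), .groups = "drop")

  q <- GenomicRanges::GRanges(site$scaffold,
                              IRanges::IRanges(site$position, site$position))
  windows <- GenomicRanges::GRanges(
    gene_set$scaffold,
    IRanges::IRanges(pmax(1L, gene_set$start - as.integer(flank)),
                     gene_set$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(q, windows)
  if (length(hits) == 0) {
    abort("no covered sites fall within any gene window")
  }
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  gene <- gene_set[gi, ]
  pos <- site$position[si]
  len <- gene$end - gene$start + 1

  # signed distance from the TSS in transcription direction
  rel <- ifelse(gene$strand == "+", pos - gene$start, gene$end - pos)
  region <- dplyr::case_when(
    rel < 0 ~ "upstream",
    rel >= len ~ "downstream",
    TRUE ~ "body"
  )
  # flank bins count 1-based distance from the gene edge, so the layout is
  # symmetric under strand reversal
  bin <- integer(length(rel))
  up <- region == "upstream"
  bin[up] <- n_flank_bins + 1L - as.integer(ceiling(-rel[up] / flank_bin_bp))
  body <- region == "body"
  # midpoint binning keeps the body scale symmetric under strand reversal
  bin[body] <- n_flank_bins + 1L +
    pmin(body_bins - 1L,
         floor((rel[body] + 0.5) / len[body] * body_bins))
  down <- region == "downstream"
  bin[down] <- n_flank_bins + body_bins +
    as.integer(ceiling((rel[down] - len[down] + 1L) / flank_bin_bp))

  keep <- bin >= 1 & bin <= 2L * n_flank_bins + body_bins
  per_gene <- tibble(gene_id = gene$gene_id[keep], bin = bin[keep],
                     fraction = site$fraction[si][keep]) |>
    group_by(.data$gene_id, .data$bin) |>
    summarise(fraction = mean(.data$fraction), n_sites = n(),
              .groups = "drop")
  prof <- per_gene |>
    group_by(.data$bin) |>
    summarise(mean_fraction = mean(.data$fraction),
              n_sites = sum(.data$n_sites), n_genes = n(),
              .groups = "drop") |>
    mutate(region = dplyr::case_when(
      .data$bin <= n_flank_bins ~ "upstream",
      .data$bin <= n_flank_bins + body_bins ~ "body",
      TRUE ~ "downstream"
    )) |>
    select("bin", "region", "mean_fraction", "n_sites", "n_genes")
  attr(prof, "layout") <- list(flank = flank, body_bins = body_bins,
                               flank_bin_bp = flank_bin_bp,
                               n_flank_bins = n_flank_bins)
  structure(prof, class = c("metagene_profile", class(tibble())))
}

#' Gene body methylation rate (GBMR)
#'
#' Mean CpG methylation fraction over each annotated gene span -- bedtools
#' `map -o mean` semantics: the unweighted mean of the per-site fractions of
#' covered CpGs overlapping the gene body (both ends inclusive,
#' strand-agnostic). Genes without covered CpGs get `NA` and are excluded
#' from downstream ranking. A CpG under two overlapping genes contributes to
#' both.
#'
#' @param calls A `methylation_calls` tibble (CpG context); several samples
#'   are averaged per site first.
#' @param gene_set A `gene_set` tibble.
#' @return A tibble (class `gene_methylation`) with `gene_id`, `n_sites`,
#'   `gbmr`.
#' @export
gene_body_methylation <- function(calls, gene_set) {
  site <- calls |>
    group_by(.data$scaffold, .data$position) |>
    summarise(fraction = mean(.data$fraction), .groups = "drop")
  q <- GenomicRanges::GRanges(site$scaffold,
                              IRanges::IRanges(site$position, site$position))
  s <- GenomicRanges::GRanges(gene_set$scaffold,
                              IRanges::IRanges(gene_set$start, gene_set$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  per <- tibble(gene_id = gene_set$gene_id[S4Vectors::subjectHits(hits)],
                fraction = site$fraction[S4Vectors::queryHits(hits)]) |>
    group_by(.data$gene_id) |>
    summarise(n_sites = n(), gbmr = mean(.data$fraction), .groups = "drop")
  out <- gene_set |>
    select("gene_id") |>
    left_join(per, by = "gene_id") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
  structure(out, class = c("gene_methylation", class(tibble())))
}

#' Classify genes by GBMR rank into low / mid / high
#'
#' Fractional ranks (average ranks for ties, rescaled as (rank - 1)/(n - 1)
#' so the least methylated gene sits at 0 and the most methylated at 1)
#' split the bimodal GBMR distribution: rank at or below `low_cut` (default
#' 0.2) is `low`, at or above `high_cut` (default 0.5) is `high`, between
#' the two is `mid` and excluded from enrichment contrasts. Rank is the
#' operative rule, so any strictly monotone transform of GBMR gives the same
#' classes.
#'
#' @param gene_meth A `gene_methylation` tibble; `NA` GBMRs are left
#'   unclassified.
#' @param low_cut,high_cut Rank-fraction boundaries.
#' @return The input with `rank_fraction` and `meth_class` added.
#' @export
classify_genes_by_rank <- function(gene_meth, low_cut = 0.2, high_cut = 0.5) {
  ranked <- !is.na(gene_meth$gbmr)
  assert_that(sum(ranked) >= 2, "need at least 2 genes with a GBMR to rank")
  rf <- rep(NA_real_, nrow(gene_meth))
  rf[ranked] <- (rank(gene_meth$gbmr[ranked], ties.method = "average") - 1) /
    (sum(ranked) - 1)
  cls <- rep(NA_character_, nrow(gene_meth))
  cls[ranked] <- dplyr::case_when(
    rf[ranked] <= low_cut ~ "low",
    rf[ranked] >= high_cut ~ "high",
    TRUE ~ "mid"
  )
  if (length(unique(gene_meth$gbmr[ranked])) == 1) {
    warn("all GBMRs tied; every gene classified mid")
    cls[ranked] <- "mid"
  }
  out <- mutate(gene_meth, rank_fraction = rf, meth_class = cls)
  structure(out, class = unique(c("gene_methylation", class(out))))
}

#' Reads per kilobase per million mapped reads
#'
#' `1e9 * counts / (gene_length_bp * total_mapped_reads)`.
#'
#' @param counts Read counts per gene.
#' @param gene_length_bp Gene lengths in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return RPKM values.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
rpkm <- function(counts, gene_length_bp, total_mapped_reads) {
  assert_that(all(gene_length_bp > 0), "gene_length_bp must be positive")
  assert_that(all(total_mapped_reads > 0),
              "total_mapped_reads must be positive")
  1e9 * counts / (gene_length_bp * total_mapped_reads)
}

#' Mean GBMR by gene expression rank
#'
#' Orders genes by RPKM, cuts them into `n_bins` equal-size rank bins, and
#' reports the mean GBMR per bin -- the curve relating gene-body methylation
#' to expression. The three fixed RPKM bands (< 100, 100--1000, > 1000) are
#' always reported alongside as `bin_type = "rpkm_band"` rows.
#'
#' @param gene_meth A `gene_methylation` tibble.
#' @param expression An `expression_table` (`gene_id`, `rpkm`).
#' @param n_bins Number of equal-size expression-rank bins.
#' @return A tibble with `bin_type` (`rank` or `rpkm_band`), `bin`,
#'   `mean_gbmr`, `n`, and for band rows the band label.
#' @export
methylation_by_expression_rank <- function(gene_meth, expression,
                                           n_bins = 10) {
  d <- inner_join(gene_meth, expression, by = "gene_id") |>
    filter(!is.na(.data$gbmr))
  assert_that(nrow(d) > 0, "no overlapping gene ids with a GBMR")
  d <- d |>
    mutate(r = rank(.data$rpkm, ties.method = "first"),
           bin = pmin(.env$n_bins,
                      1L + as.integer(floor((.data$r - 1) / n() * n_bins))))
  ranks <- d |>
    group_by(.data$bin) |>
    summarise(mean_gbmr = mean(.data$gbmr), n = n(), .groups = "drop") |>
    mutate(bin_type = "rank", band = NA_character_)
  bands <- d |>
    mutate(band = dplyr::case_when(
      .data$rpkm < 100 ~ "<100",
      .data$rpkm <= 1000 ~ "100-1000",
      TRUE ~ ">1000"
    )) |>
    group_by(.data$band) |>
    summarise(mean_gbmr = mean(.data$gbmr), n = n(), .groups = "drop") |>
    mutate(bin_type = "rpkm_band",
           bin = match(.data$band, c("<100", "100-1000", ">1000")))
  bind_rows(ranks, bands) |>
    select("bin_type", "bin", "band", "mean_gbmr", "n")
}

#' Ward clustering of samples on correlation distance
#'
#' Builds the per-sample methylation-fraction matrix from a united matrix,
#' computes pairwise distance `1 - Pearson correlation`, and agglomerates
#' with Ward's criterion (`stats::hclust(method = "ward.D")`, the convention
#' of methylKit's `clusterSamples`). Samples are ordered by label before
#' clustering so the result does not depend on input order.
#'
#' @param united A `united_matrix` with at least 3 samples and 2 sites.
#' @return An `hclust` object.
#' @export
cluster_samples <- function(united) {
  samples <- sort(attr(united, "samples"))
  assert_that(length(samples) >= 3, "need at least 3 samples")
  assert_that(nrow(united) >= 2, "need at least 2 united sites")
  cc <- united_counts(united, samples)
  frac <- cc$M / (cc$M + cc$U)
  sds <- apply(frac, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("constant methylation profile (undefined correlation) in: ",
                 paste(samples[sds == 0], collapse = ", ")))
  }
  d <- as.dist(1 - cor(frac))
  hclust(d, method = "ward.D")
}

#' Newick serialization of a sample dendrogram
#'
#' @param hc An `hclust` from [cluster_samples()].
#' @param path Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
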