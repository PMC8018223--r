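#' Assign DMCs to gene bodies
#'
#' DMCs overlapping an annotated gene span (both ends inclusive,
#' strand-agnostic) are assigned to that gene; a DMC under several
#' overlapping genes is assigned to each and flagged; DMCs outside every
#' gene body are discarded and counted, mirroring the study's rule that
#' positions outside gene bodies are not considered.
#'
#' @param dmcs A DMC tibble (e.g. `tidy()` of a `dmc_set`, or a
#'   non-redundant union) with site key columns and `direction`.
#' @param gene_set A `gene_set` tibble.
#' @return A tibble with `gene_id`, `n_hyper`, `n_hypo`, `n_dmc`,
#'   `multi_assigned` (any of the gene's DMCs was shared with another gene).
#'   Attributes: `n_intergenic` (discard counter) and `assignments` (the
#'   per-DMC gene assignment table).
#' @export
map_dmcs_to_genes <- function(dmcs, gene_set) {
  if (nrow(dmcs) == 0) {
    out <- tibble(gene_id = character(), n_hyper = integer(),
                  n_hypo = integer(), n_dmc = integer(),
                  multi_assigned = logical())
    attr(out, "n_intergenic") <- 0L
    return(out)
  }
  q <- GenomicRanges::GRanges(dmcs$scaffold,
                              IRanges::IRanges(dmcs$position, dmcs$position))
  s <- GenomicRanges::GRanges(gene_set$scaffold,
                              IRanges::IRanges(gene_set$start, gene_set$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  di <- S4Vectors::queryHits(hits)
  assignments <- tibble(
    scaffold = dmcs$scaffold[di], position = dmcs$position[di],
    strand = dmcs$strand[di], direction = dmcs$direction[di],
    gene_id = gene_set$gene_id[S4Vectors::subjectHits(hits)]
  ) |>
    group_by(.data$scaffold, .data$position, .data$strand,
             .data$direction) |>
    mutate(multi_assigned = n() > 1) |>
    ungroup()
  out <- assignments |>
    group_by(.data$gene_id) |>
    summarise(
      n_hyper = sum(.data$direction == "hyper"),
      n_hypo = sum(.data$direction == "hypo"),
      n_dmc = n(),
      multi_assigned = any(.data$multi_assigned),
      .groups = "drop"
    )
  attr(out, "n_intergenic") <- nrow(dmcs) - dplyr::n_distinct(
    dmcs$scaffold[di], dmcs$position[di], dmcs$strand[di])
  attr(out, "assignments") <- assignments
  out
}

#' GO term over-representation by Fisher's exact test
#'
#' For every term annotated to at least one study gene, tests enrichment of
#' the term in the study set against the population with a one-sided
#' (greater) Fisher exact test on the 2x2 table (study-with-term,
#' study-without, rest-with-term, rest-without); the p-value is the upper
#' hypergeometric tail. q-values are Benjamini-Hochberg, adjusted within
#' each namespace separately (BP and MF are reported as separate families).
#' No ancestor propagation is applied: terms are tested as annotated.
#'
#' @param study_genes Character vector of study gene ids (must be a subset
#'   of the population).
#' @param population_genes Character vector of population gene ids.
#' @param annotation Tibble with `gene_id`, `go_id` and optionally
#'   `namespace` (defaults to a single namespace) and `term_name`.
#' @return A tibble (class `go_enrichment`) sorted by p: `go_id`,
#'   `namespace`, `study_count`, `study_n`, `pop_count`, `pop_n`, `p`, `q`.
#' @export
go_enrichment <- function(study_genes, population_genes, annotation) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  assert_that(length(study_genes) > 0, "study gene set is empty")
  extra <- setdiff(study_genes, population_genes)
  if (length(extra)) {
    abort(paste0("study genes missing from population: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  if (!"namespace" %in% names(annotation)) annotation$namespace <- "ALL"
  ann <- annotation |>
    filter(.data$gene_id %in% population_genes) |>
    distinct(.data$gene_id, .data$go_id, .data$namespace)
  study_n <- length(study_genes)
  pop_n <- length(population_genes)
  res <- ann |>
    group_by(.data$go_id, .data$namespace) |>
    summarise(
      study_count = sum(.data$gene_id %in% study_genes),
      pop_count = n(),
      .groups = "drop"
    ) |>
    filter(.data$study_count >= 1) |>
    mutate(
      study_n = study_n, pop_n = pop_n,
      p = phyper(.data$study_count - 1, .data$pop_count,
                 pop_n - .data$pop_count, study_n, lower.tail = FALSE)
    ) |>
    group_by(.data$namespace) |>
    mutate(q = adjust_qvalues(.data$p)) |>
    ungroup() |>
    arrange(.data$p) |>
    select("go_id", "namespace", "study_count", "study_n", "pop_count",
           "pop_n", "p", "q")
  if ("term_name" %in% names(annotation)) {
    res <- left_join(res,
                     distinct(annotation, .data$go_id, .data$term_name),
                     by = "go_id")
  }
  structure(res, class = c("go_enrichment", class(tibble())))
}

#' Read a two-column gene-to-GO map
#'
#' Tab-separated `gene_id`, `go_id`, with optional third column
#' `namespace`.
#'
#' @param path TSV path.
#' @return An annotation tibble.
#' @export
read_go_map <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  assert_that(all(c("gene_id", "go_id") %in% names(d)),
              "GO map needs gene_id and go_id columns")
  d
}
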