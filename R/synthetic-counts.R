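#' The full factorial sample design of the yo-yo experiment
#'
#' Three genotypes (families), a control group held at 8 m and a treatment
#' group cycled 8 m / 30 m / 8 m, each individual sampled at three monthly
#' transfer times: 6 individuals x 3 times = 18 samples.
#'
#' @param n_genotypes Number of genotypes (families).
#' @param treatments Treatment labels (control first by convention).
#' @param n_times Number of sampling times, labelled `S1`, `S2`, ...
#' @return A tibble (class `sample_design`) with `sample_id`, `genotype`,
#'   `treatment`, `time`. Sample ids look like `"C1-S1"`.
#' @export
#' @examples
#' sample_design()
sample_design <- function(n_genotypes = 3, treatments = c("C", "T"),
                          n_times = 3) {
  d <- tidyr::expand_grid(
    treatment = treatments,
    genotype = seq_len(n_genotypes),
    time = sprintf("S%d", seq_len(n_times))
  ) |>
    mutate(sample_id = sprintf("%s%d-%s", .data$treatment, .data$genotype,
                               .data$time)) |>
    select("sample_id", "genotype", "treatment", "time")
  class(d) <- c("sample_design", class(d))
  d
}

#' Read / write a sample design TSV
#' @param path TSV with columns `sample_id`, `genotype`, `treatment`, `time`.
#' @return A `sample_design` tibble (reader); `path` invisibly (writer).
#' @export
read_sample_design <- function(path) {
  d <- readr::read_tsv(path, col_types = "cicc", progress = FALSE)
  assert_that(all(c("sample_id", "genotype", "treatment", "time") %in%
                    names(d)), "design file must have sample_id/genotype/treatment/time")
  assert_that(!anyDuplicated(d$sample_id), "duplicate sample_id in design")
  class(d) <- c("sample_design", class(d))
  d
}

#' @rdname read_sample_design
#' @param design A `sample_design` tibble.
#' @export
write_sample_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Simulate per-cytosine bisulfite counts for every sample
#'
#' For each sample the true fraction at a site is the methylome level, plus a
#' per-genotype random offset (shared by all samples of that genotype), plus
#' any planted shift matching the sample's (treatment, time), clamped to
#' \[0,1\]. Coverage is negative-binomial (mean `coverage_mean`, size
#' `coverage_dispersion`) -- overdispersed relative to Poisson, so the
#' minimum-coverage filter downstream has something to do. The observed
#' methylated count is binomial in the coverage with success probability
#' `f * (1 - e) + (1 - f) * e`, a symmetric bisulfite conversion error `e`.
#'
#' @param methylome A `true_methylome`, optionally with planted DMCs.
#' @param design A [sample_design()].
#' @param config A [synthetic_config()].
#' @return A long tibble (class `cytosine_reports`) with one row per site per
#'   sample: `sample_id`, `scaffold`, `position`, `strand`, `context`,
#'   `trinucleotide`, `count_methylated`, `count_unmethylated`. Sample
#'   metadata stays joinable through `design`.
#' @export
simulate_counts <- function(methylome, design, config) {
  validate_synthetic_config(config)
  n_sites <- nrow(methylome)
  planted <- planted_truth(methylome)
  with_seed(config$seed + 4L, {
    genos <- sort(unique(design$genotype))
    geno_offset <- matrix(rnorm(n_sites * length(genos), 0, config$genotype_sd),
                          nrow = n_sites,
                          dimnames = list(NULL, as.character(genos)))
    # index of each planted site in the methylome
    pk <- match(paste(planted$scaffold, planted$position, planted$strand),
                paste(methylome$scaffold, methylome$position, methylome$strand))
    purrr::map_dfr(seq_len(nrow(design)), function(j) {
      smp <- design[j, ]
      f <- methylome$level + geno_offset[, as.character(smp$genotype)]
      if (nrow(planted)) {
        hit <- planted$affected_group == smp$treatment &
          vapply(strsplit(planted$affected_times, ",", fixed = TRUE),
                 function(tt) smp$time %in% tt, logical(1))
        f[pk[hit]] <- f[pk[hit]] + planted$delta_points[hit] / 100
      }
      f <- clamp01(f)
      p_obs <- f * (1 - config$conversion_error) +
        (1 - f) * config$conversion_error
      coverage <- rnbinom(n_sites, mu = config$coverage_mean,
                          size = config$coverage_dispersion)
      m <- rbinom(n_sites, coverage, p_obs)
      tibble(
        sample_id = smp$sample_id,
        scaffold = methylome$scaffold, position = methylome$position,
        strand = methylome$strand, context = methylome$context,
        trinucleotide = methylome$trinucleotide,
        count_methylated = m, count_unmethylated = coverage - m
      )
    }) |>
      structure(class = c("cytosine_reports", class(tibble())))
  })
}

#' Simulate a gene expression table
#'
#' With `coupling = "hump"`, genes of mid-to-high methylation are
#' preferentially assigned RPKM in the moderately expressed 100--1000 band,
#' so the methylation-by-expression-rank curve shows the hump typical of
#' invertebrate gene-body methylation; lowly methylated genes land in the
#' outer bands. With `coupling = "none"` RPKM is independent of class.
#'
#' @param gene_set A `gene_set` tibble.
#' @param gene_meth_class Tibble with `gene_id`, `gene_class` (as produced by
#'   [assign_methylome()]'s `gene_classes` attribute).
#' @param coupling `"hump"` or `"none"`.
#' @param seed Seed.
#' @return A tibble (class `expression_table`) with `gene_id`, `rpkm`.
#' @export
simulate_expression <- function(gene_set, gene_meth_class,
                                coupling = c("hump", "none"), seed = NULL) {
  coupling <- match.arg(coupling)
  if (nrow(gene_set) == 0) {
    return(structure(tibble(gene_id = character(), rpkm = double()),
                     class = c("expression_table", class(tibble()))))
  }
  cls <- gene_meth_class$gene_class[match(gene_set$gene_id,
                                          gene_meth_class$gene_id)]
  with_seed(seed, {
    n <- nrow(gene_set)
    rpkm <- if (coupling == "none") {
      10^runif(n, -1, 4)
    } else {
      ifelse(cls %in% c("high", "mid"),
             10^runif(n, log10(100), log10(1000)),
             ifelse(runif(n) < 0.5, 10^runif(n, -1, log10(100)),
                    10^runif(n, log10(1000), 4)))
    }
    structure(tibble(gene_id = gene_set$gene_id, rpkm = rpkm),
              class = c("expression_table", class(tibble())))
  })
}

#' Simulate a gene-to-GO annotation map
#'
#' Random annotation of genes with GO-like terms in two namespaces (BP, MF),
#' used to exercise the enrichment stage on synthetic data.
#'
#' @param gene_set A `gene_set` tibble.
#' @param n_terms Number of distinct terms.
#' @param mean_terms_per_gene Poisson mean of annotations per gene.
#' @param seed Seed.
#' @return A tibble with `gene_id`, `go_id`, `namespace`.
#' @export
simulate_go_map <- function(gene_set, n_terms = 40,
                            mean_terms_per_gene = 3, seed = NULL) {
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    ns <- sample(c("BP", "MF"), n_terms, replace = TRUE)
    purrr::map_dfr(gene_set$gene_id, function(g) {
      k <- min(rpois(1, mean_terms_per_gene), n_terms)
      if (k == 0) return(tibble())
      idx <- sample.int(n_terms, k)
      tibble(gene_id = g, go_id = terms[idx], namespace = ns[idx])
    })
  })
}
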