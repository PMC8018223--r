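#' Configuration for the synthetic bisulfite study generator
#'
#' Bundles every tunable of the synthetic-data module: genome geometry, the
#' bimodal gene-body methylation model of a mosaic invertebrate methylome,
#' per-context background methylation, the sequencing noise model, and the
#' yo-yo factorial design (genotypes x treatments x sampling times).
#'
#' The defaults emulate a mosaic methylome: CpG methylation concentrated in
#' gene bodies with a bimodal gene-level distribution (a lowly methylated mode
#' at 0--0.19% and a highly methylated mode at 0.5--40.12%), near-zero CHG/CHH
#' methylation (about 1%), and a modest intergenic CpG background, sampled by
#' three genotypes under control/treatment across three monthly sampling
#' times.
#'
#' @param n_scaffolds Number of scaffolds in the synthetic genome.
#' @param scaffold_length Length of each scaffold in bp (minimum 1000).
#' @param gc GC fraction used when drawing bases.
#' @param n_genes Total number of non-overlapping gene models to place.
#' @param gene_length_range Length-2 vector, min/max gene length in bp.
#' @param flank Flank size in bp used around genes (metagene convention).
#' @param low_gene_fraction,high_gene_fraction Proportions of genes assigned
#'   to the lowly / highly methylated class. Must sum to at most 1; any
#'   remainder becomes a "mid" class drawn from `high_level_range`.
#' @param low_level_range,high_level_range Methylation-fraction ranges for the
#'   two gene classes. The low maximum must stay below the high minimum so
#'   bimodality is constructible.
#' @param intergenic_level CpG methylation fraction outside gene bodies.
#' @param chg_level,chh_level Background methylation fractions for CHG/CHH.
#' @param coverage_mean Mean per-site read coverage.
#' @param coverage_dispersion Negative-binomial size parameter for coverage
#'   (smaller = more overdispersed than Poisson).
#' @param conversion_error Symmetric bisulfite conversion error rate: a truly
#'   unmethylated read is called methylated with this probability and vice
#'   versa.
#' @param genotype_sd Standard deviation of the per-genotype, per-site offset
#'   added to true fractions (gives genotype structure to clustering).
#' @param n_genotypes,n_times Number of genotypes and sampling times.
#' @param treatments Treatment labels; default control `"C"` and depth
#'   treatment `"T"`.
#' @param planted_effect_size Default methylation shift, in percentage points,
#'   for planted differentially methylated cytosines. Keep above 25 when the
#'   planted sites must clear the downstream difference filter.
#' @param n_planted_dmcs Default number of planted DMCs.
#' @param seed Integer seed; identical configuration + seed reproduces every
#'   generated object byte for byte.
#'
#' @return A `synthetic_config` list, validated.
#' @export
#' @examples
#' cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 10000,
#'                         n_genes = 5, seed = 1)
synthetic_config <- function(n_scaffolds = 4,
                             scaffold_length = 50000,
                             gc = 0.35,
                             n_genes = 40,
                             gene_length_range = c(1000, 3000),
                             flank = 3000,
                             low_gene_fraction = 0.2,
                             high_gene_fraction = 0.8,
                             low_level_range = c(0.0000, 0.0019),
                             high_level_range = c(0.005, 0.4012),
                             intergenic_level = 0.03,
                             chg_level = 0.009,
                             chh_level = 0.010,
                             coverage_mean = 30,
                             coverage_dispersion = 5,
                             conversion_error = 0.005,
                             genotype_sd = 0.01,
                             n_genotypes = 3,
                             n_times = 3,
                             treatments = c("C", "T"),
                             planted_effect_size = 30,
                             n_planted_dmcs = 50,
                             seed = 1L) {
  cfg <- list(
    n_scaffolds = n_scaffolds, scaffold_length = scaffold_length, gc = gc,
    n_genes = n_genes, gene_length_range = gene_length_range, flank = flank,
    low_gene_fraction = low_gene_fraction,
    high_gene_fraction = high_gene_fraction,
    low_level_range = low_level_range, high_level_range = high_level_range,
    intergenic_level = intergenic_level,
    chg_level = chg_level, chh_level = chh_level,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    conversion_error = conversion_error, genotype_sd = genotype_sd,
    n_genotypes = n_genotypes, n_times = n_times, treatments = treatments,
    planted_effect_size = planted_effect_size,
    n_planted_dmcs = n_planted_dmcs, seed = seed
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  assert_that(cfg$n_scaffolds >= 1, "n_scaffolds must be >= 1")
  assert_that(cfg$scaffold_length >= 1000, "scaffold_length must be >= 1000")
  assert_that(cfg$gc > 0 && cfg$gc < 1, "gc must be in (0, 1)")
  assert_that(cfg$n_genes >= 0, "n_genes must be non-negative")
  assert_that(length(cfg$gene_length_range) == 2 &&
                cfg$gene_length_range[1] <= cfg$gene_length_range[2] &&
                cfg$gene_length_range[1] >= 1,
              "gene_length_range must be an increasing positive pair")
  fracs <- c(cfg$low_gene_fraction, cfg$high_gene_fraction,
             cfg$intergenic_level, cfg$chg_level, cfg$chh_level,
             cfg$conversion_error, cfg$low_level_range, cfg$high_level_range)
  assert_that(all(fracs >= 0 & fracs <= 1), "all fractions must be in [0, 1]")
  assert_that(cfg$low_gene_fraction + cfg$high_gene_fraction <= 1,
              "low_gene_fraction + high_gene_fraction must not exceed 1")
  assert_that(cfg$low_level_range[2] < cfg$high_level_range[1],
              "low_level_range max must lie below high_level_range min (bimodality)")
  assert_that(cfg$coverage_mean >= 0, "coverage_mean must be non-negative")
  assert_that(cfg$coverage_dispersion > 0, "coverage_dispersion must be positive")
  assert_that(cfg$n_genotypes >= 1 && cfg$n_times >= 1,
              "n_genotypes and n_times must be >= 1")
  assert_that(length(cfg$treatments) >= 1 && !anyDuplicated(cfg$treatments),
              "treatments must be unique labels")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  genome: %d scaffold(s) x %d bp (GC %.2f), %d genes\n",
              x$n_scaffolds, x$scaffold_length, x$gc, x$n_genes))
  cat(sprintf("  methylome: low %.4f-%.4f / high %.4f-%.4f, intergenic %.3f\n",
              x$low_level_range[1], x$low_level_range[2],
              x$high_level_range[1], x$high_level_range[2],
              x$intergenic_level))
  cat(sprintf("  design: %d genotypes x {%s} x %d times; coverage NB(mu=%g, size=%g)\n",
              x$n_genotypes, paste(x$treatments, collapse = ","),
              x$n_times, x$coverage_mean, x$coverage_dispersion))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}
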