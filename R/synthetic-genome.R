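#' Generate a synthetic genome
#'
#' Draws independent bases with the configured GC fraction and returns a
#' [Biostrings::DNAStringSet] with scaffolds named `scf01`, `scf02`, ...
#'
#' @param config A [synthetic_config()].
#' @return A `DNAStringSet` of `n_scaffolds` sequences.
#' @export
#' @examples
#' gen <- generate_genome(synthetic_config(n_scaffolds = 1,
#'                                         scaffold_length = 2000, seed = 1))
generate_genome <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_scaffolds
  len <- config$scaffold_length
  gc <- config$gc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(config$seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("scf%02d", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Write / read a genome as FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly (writer); a `DNAStringSet` (reader).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Generate non-overlapping gene models
#'
#' Places `n_genes` disjoint genes across the scaffolds (round-robin), with
#' lengths drawn uniformly from `gene_length_range` and random strands. Gene
#' starts are placed by distributing the leftover scaffold length uniformly
#' among the gaps, so genes land anywhere feasibility allows. Fails when the
#' requested genes cannot be packed.
#'
#' @param genome A `DNAStringSet` from [generate_genome()].
#' @param config A [synthetic_config()].
#' @return A tibble (class `gene_set`) with columns `gene_id`, `scaffold`,
#'   `start`, `end` (1-based inclusive), `strand`, `length`, `tss`, `tes`.
#'   For minus-strand genes the TSS is the higher coordinate.
#' @export
generate_gene_models <- function(genome, config) {
  validate_synthetic_config(config)
  n_genes <- config$n_genes
  scaffolds <- names(genome)
  lens <- Biostrings::width(genome)
  if (n_genes == 0) {
    empty <- tibble(gene_id = character(), scaffold = character(),
                    start = integer(), end = integer(), strand = character(),
                    length = integer(), tss = integer(), tes = integer())
    class(empty) <- c("gene_set", class(empty))
    return(empty)
  }
  # round-robin assignment of gene counts per scaffold
  per_scaf <- tabulate(rep(seq_along(scaffolds), length.out = n_genes),
                       nbins = length(scaffolds))
  with_seed(config$seed + 1L, {
    rows <- purrr::map_dfr(seq_along(scaffolds), function(i) {
      k <- per_scaf[i]
      if (k == 0) return(tibble())
      span <- config$gene_length_range[2] - config$gene_length_range[1] + 1L
      glen <- config$gene_length_range[1] +
        sample.int(span, k, replace = TRUE) - 1L
      slack <- lens[i] - sum(glen)
      if (slack < k + 1) {
        abort(sprintf(
          "cannot place %d genes totalling %d bp on scaffold %s (%d bp)",
          k, sum(glen), scaffolds[i], lens[i]))
      }
      # distribute the slack among k+1 gaps (each gap >= 1 bp)
      cuts <- sort(sample.int(slack - 1, k))
      gaps <- diff(c(0, cuts, slack))
      starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, glen[-k])) + 1
      tibble(
        scaffold = scaffolds[i],
        start = starts,
        end = starts + glen - 1,
        strand = sample(c("+", "-"), k, replace = TRUE),
        length = glen
      )
    })
    rows <- rows |>
      arrange(.data$scaffold, .data$start) |>
      mutate(
        gene_id = sprintf("g%03d", row_number()),
        tss = if_else(.data$strand == "+", .data$start, .data$end),
        tes = if_else(.data$strand == "+", .data$end, .data$start)
      ) |>
      select("gene_id", "scaffold", "start", "end", "strand",
             "length", "tss", "tes")
    class(rows) <- c("gene_set", class(rows))
    rows
  })
}

#' Write gene models as GFF3 or BED6
#'
#' GFF3 keeps the internal 1-based inclusive coordinates; BED output is
#' converted to 0-based half-open.
#'
#' @param genes A `gene_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmosaicmeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$scaffold, genes$start, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
write_gene_models_bed <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   genes$scaffold, genes$start - 1L, genes$end,
                   genes$gene_id, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 or BED file
#'
#' @param path Input path.
#' @param format `"gff3"` or `"bed"`.
#' @return A `gene_set` tibble as from [generate_gene_models()].
#' @export
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 9)
    if (length(bad)) abort(sprintf("malformed GFF3 line %d", bad[1]))
    ids <- sub("^.*ID=([^;]+).*$", "\\1", vapply(parts, `[[`, "", 9))
    g <- tibble(
      gene_id = ids,
      scaffold = vapply(parts, `[[`, "", 1),
      start = as.integer(vapply(parts, `[[`, "", 4)),
      end = as.integer(vapply(parts, `[[`, "", 5)),
      strand = vapply(parts, `[[`, "", 7)
    )
  } else {
    g <- readr::read_tsv(path, col_names = c("scaffold", "start0", "end",
                                             "gene_id", "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
    g <- tibble(
      gene_id = g$gene_id, scaffold = g$scaffold,
      start = g$start0 + 1L, end = as.integer(g$end), strand = g$strand
    )
  }
  g <- g |>
    mutate(length = .data$end - .data$start + 1L,
           tss = if_else(.data$strand == "+", .data$start, .data$end),
           tes = if_else(.data$strand == "+", .data$end, .data$start))
  class(g) <- c("gene_set", class(g))
  g
}
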