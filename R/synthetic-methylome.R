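COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# context from the two strand-aware downstream bases (3' of the cytosine)
context_from_next <- function(n1, n2) {
  ctx <- rep("CHN", length(n1))
  known1 <- !is.na(n1) & n1 != "N"
  ctx[known1 & n1 == "G"] <- "CpG"
  h1 <- known1 & n1 != "G"
  known2 <- h1 & !is.na(n2) & n2 != "N"
  ctx[known2 & n2 == "G"] <- "CHG"
  ctx[known2 & n2 != "G"] <- "CHH"
  ctx
}

# Every cytosine of the genome, per strand, with its context and
# trinucleotide. The workhorse behind assign_methylome() and the genome-aware
# parts of the calling module.
enumerate_cytosines <- function(genome) {
  purrr::map_dfr(seq_along(genome), function(i) {
    ch <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
    len <- length(ch)
    nm <- names(genome)[i]
    at <- function(pos) ifelse(pos >= 1 & pos <= len, ch[pmax(pmin(pos, len), 1)], NA)
    # plus strand: cytosines read left to right
    p <- which(ch == "C")
    n1p <- at(p + 1); n2p <- at(p + 2)
    # minus strand: genomic G, read right to left on the complement
    m <- which(ch == "G")
    n1m <- unname(COMPLEMENT[at(m - 1)]); n2m <- unname(COMPLEMENT[at(m - 2)])
    tri <- function(a, b) paste0("C", ifelse(is.na(a), "N", a),
                                 ifelse(is.na(b), "N", b))
    bind_rows(
      tibble(scaffold = nm, position = p, strand = "+",
             context = context_from_next(n1p, n2p),
             trinucleotide = tri(n1p, n2p)),
      tibble(scaffold = nm, position = m, strand = "-",
             context = context_from_next(n1m, n2m),
             trinucleotide = tri(n1m, n2m))
    ) |> arrange(.data$position, .data$strand)
  })
}

#' Assign true methylation levels to every cytosine
#'
#' Builds the "true" methylome the simulator samples from. Gene classes are
#' drawn per gene (low / high, in the configured proportions); CpGs inside a
#' gene all receive that gene's level, drawn uniformly from the class range;
#' intergenic CpGs get `intergenic_level`; CHG/CHH cytosines get the
#' configured background everywhere. The resulting distribution of per-gene
#' mean CpG levels is bimodal by construction, with an empty band between the
#' low maximum and the high minimum.
#'
#' @param genome A `DNAStringSet`.
#' @param gene_set A `gene_set` tibble.
#' @param config A [synthetic_config()].
#' @return A tibble (class `true_methylome`) with one row per cytosine per
#'   strand: `scaffold`, `position`, `strand`, `context`, `trinucleotide`,
#'   `gene_id` (NA when intergenic), `gene_class`, `level`.
#' @export
assign_methylome <- function(genome, gene_set, config) {
  validate_synthetic_config(config)
  sites <- enumerate_cytosines(genome)
  with_seed(config$seed + 2L, {
    n_low <- round(config$low_gene_fraction * nrow(gene_set))
    n_high <- round(config$high_gene_fraction * nrow(gene_set))
    n_high <- min(n_high, nrow(gene_set) - n_low)
    classes <- sample(c(rep("low", n_low), rep("high", n_high),
                        rep("mid", nrow(gene_set) - n_low - n_high)))
    glevel <- ifelse(
      classes == "low",
      runif(nrow(gene_set), config$low_level_range[1], config$low_level_range[2]),
      runif(nrow(gene_set), config$high_level_range[1], config$high_level_range[2])
    )
    genes <- gene_set |>
      mutate(gene_class = classes, gene_level = glevel)

    hit <- overlap_gene(sites$scaffold, sites$position, genes)
    sites <- sites |>
      mutate(gene_id = genes$gene_id[hit],
             gene_class = genes$gene_class[hit],
             level = dplyr::case_when(
               .data$context %in% c("CHG", "CHN") ~ config$chg_level,
               .data$context == "CHH" ~ config$chh_level,
               !is.na(hit) ~ genes$gene_level[hit],
               TRUE ~ config$intergenic_level
             ))
    attr(sites, "gene_classes") <- genes |>
      select("gene_id", "gene_class", "gene_level")
    class(sites) <- c("true_methylome", class(sites))
    sites
  })
}

# first overlapping gene index for each (scaffold, position); NA if none
overlap_gene <- function(scaffold, position, genes) {
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(position, position))
  s <- GenomicRanges::GRanges(genes$scaffold,
                              IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  as.integer(hits)
}

#' Plant differentially methylated cytosines into a true methylome
#'
#' Selects genic CpGs and shifts their true level by `delta_points`
#' percentage points, but only for samples in `affected_group` at
#' `affected_times` -- the structure of a depth-specific methylation response.
#' The planted truth is recorded so recovery can be scored later.
#'
#' @param methylome A `true_methylome` from [assign_methylome()].
#' @param n_sites Number of CpGs to plant.
#' @param delta_points Shift in percentage points (positive = hyper in the
#'   affected group). Shifts leaving \[0,1\] are clipped and flagged in the
#'   truth table.
#' @param affected_group Treatment label whose samples carry the shift.
#' @param affected_times Character vector of affected sampling times.
#' @param target_gene_ids Optional gene ids to restrict planting to.
#' @param seed Seed for site selection.
#' @return The methylome with a `planted` attribute: a truth-table tibble of
#'   `scaffold`, `position`, `strand`, `gene_id`, `base_level`,
#'   `planted_level`, `delta_points`, `affected_group`, `affected_times`
#'   (comma-separated), `clipped`. Retrieve it with [planted_truth()].
#' @export
plant_dmcs <- function(methylome, n_sites, delta_points,
                       affected_group = "T", affected_times = c("S2", "S3"),
                       target_gene_ids = NULL, seed = NULL) {
  pool <- methylome |>
    filter(.data$context == "CpG", !is.na(.data$gene_id))
  if (!is.null(target_gene_ids)) {
    pool <- filter(pool, .data$gene_id %in% target_gene_ids)
  }
  if (n_sites > nrow(pool)) {
    abort(sprintf("requested %d planted sites but only %d genic CpGs available",
                  n_sites, nrow(pool)))
  }
  with_seed(seed, {
    picked <- pool[sample.int(nrow(pool), n_sites), ]
    raw <- picked$level + delta_points / 100
    shifted <- clamp01(raw)
    clipped <- shifted != raw
    if (any(clipped)) {
      warn(sprintf("%d planted site(s) clipped to [0, 1]", sum(clipped)))
    }
    truth <- tibble(
      scaffold = picked$scaffold, position = picked$position,
      strand = picked$strand, gene_id = picked$gene_id,
      base_level = picked$level, planted_level = shifted,
      delta_points = delta_points,
      affected_group = affected_group,
      affected_times = paste(affected_times, collapse = ","),
      clipped = clipped
    )
    attr(methylome, "planted") <- bind_rows(planted_truth(methylome), truth)
    methylome
  })
}

#' Truth table of planted DMCs
#' @param methylome A `true_methylome`.
#' @return The planted-site truth table (empty tibble if nothing planted).
#' @export
planted_truth <- function(methylome) {
  attr(methylome, "planted") %||%
    tibble(scaffold = character(), position = integer(), strand = character(),
           gene_id = character(), base_level = double(),
           planted_level = double(), delta_points = double(),
           affected_group = character(), affected_times = character(),
           clipped = logical())
}

#' Write a planted-DMC truth table as TSV
#' @param methylome A `true_methylome` with planted sites.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(methylome, path) {
  readr::write_tsv(planted_truth(methylome), path, progress = FALSE)
  invisible(path)
}
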