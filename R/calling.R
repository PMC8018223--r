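#' Write per-cytosine counts in Bismark dialects
#'
#' `cx_report`: scaffold, 1-based position, strand, count methylated, count
#' unmethylated, context, trinucleotide. `coverage`: scaffold, start, end
#' (both the 1-based position), percent methylation, count methylated, count
#' unmethylated; coverage lines with zero total coverage are written with
#' percent 0.
#'
#' @param reports A `cytosine_reports` tibble (long, with `sample_id`) or a
#'   single-sample report.
#' @param dir Output directory; one file per sample,
#'   `<sample_id>.CX_report.txt` or `<sample_id>.cov`.
#' @param dialect `"cx_report"` or `"coverage"`.
#' @return File paths, invisibly.
#' @export
write_cytosine_reports <- function(reports, dir,
                                   dialect = c("cx_report", "coverage")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!"sample_id" %in% names(reports)) reports$sample_id <- "sample"
  paths <- purrr::map_chr(split(reports, reports$sample_id), function(r) {
    if (dialect == "cx_report") {
      p <- file.path(dir, paste0(r$sample_id[1], ".CX_report.txt"))
      lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s",
                       r$scaffold, r$position, r$strand,
                       r$count_methylated, r$count_unmethylated,
                       r$context, r$trinucleotide)
    } else {
      p <- file.path(dir, paste0(r$sample_id[1], ".cov"))
      tot <- r$count_methylated + r$count_unmethylated
      pct <- ifelse(tot > 0, 100 * r$count_methylated / tot, 0)
      lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                       r$scaffold, r$position, r$position,
                       format(pct, trim = TRUE), r$count_methylated,
                       r$count_unmethylated)
    }
    writeLines(lines, p)
    p
  })
  invisible(unname(paths))
}

#' Read a per-cytosine count file
#'
#' Parses the Bismark cytosine-report (`cx_report`) or coverage dialect into
#' a tidy per-site count table. Coverage files carry no strand or context; if
#' a genome is supplied both are recovered from the sequence, otherwise the
#' strand is set to `"+"` and the context to `"CHN"` (unknown).
#'
#' @param path Input file.
#' @param dialect `"cx_report"` or `"coverage"`.
#' @param sample_id Sample label; defaults to the file name.
#' @param genome Optional `DNAStringSet` for context assignment of coverage
#'   files.
#' @return A tibble (class `cytosine_reports`) with `sample_id`, `scaffold`,
#'   `position`, `strand`, `context`, `trinucleotide`, `count_methylated`,
#'   `count_unmethylated`.
#' @export
read_cytosine_report <- function(path, dialect = c("cx_report", "coverage"),
                                 sample_id = NULL, genome = NULL) {
  dialect <- match.arg(dialect)
  sample_id <- sample_id %||%
    sub("\\.(CX_report\\.txt|cov|txt|tsv)$", "", basename(path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    out <- tibble(sample_id = character(), scaffold = character(),
                  position = integer(), strand = character(),
                  context = character(), trinucleotide = character(),
                  count_methylated = integer(), count_unmethylated = integer())
    return(structure(out, class = c("cytosine_reports", class(tibble()))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (dialect == "cx_report") 7L else 6L
  bad <- which(lengths(parts) != want)
  if (length(bad)) {
    abort(sprintf("malformed %s line %d in %s: expected %d fields, got %d",
                  dialect, bad[1], path, want, lengths(parts)[bad[1]]))
  }
  field <- function(i) vapply(parts, `[[`, "", i)
  int_field <- function(i, what) {
    v <- suppressWarnings(as.integer(field(i)))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      abort(sprintf("line %d: %s must be a non-negative integer", bad[1], what))
    }
    v
  }
  if (dialect == "cx_report") {
    strand <- field(3)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) abort(sprintf("line %d: unknown strand symbol '%s'",
                                   bad[1], strand[bad[1]]))
    ctx <- field(6)
    bad <- which(!ctx %in% CONTEXTS & ctx != "CN")
    if (length(bad)) abort(sprintf("line %d: unknown context '%s'",
                                   bad[1], ctx[bad[1]]))
    out <- tibble(
      sample_id = sample_id, scaffold = field(1),
      position = int_field(2, "position"), strand = strand,
      context = ifelse(ctx == "CN", "CHN", ctx), trinucleotide = field(7),
      count_methylated = int_field(4, "count_methylated"),
      count_unmethylated = int_field(5, "count_unmethylated")
    )
  } else {
    pos <- int_field(2, "position")
    out <- tibble(
      sample_id = sample_id, scaffold = field(1), position = pos,
      strand = "+", context = "CHN", trinucleotide = "CNN",
      count_methylated = int_field(5, "count_methylated"),
      count_unmethylated = int_field(6, "count_unmethylated")
    )
    if (!is.null(genome)) {
      base <- genome_base(genome, out$scaffold, out$position)
      out$strand <- ifelse(base == "G", "-", "+")
      out$context <- assign_context(genome, out$scaffold, out$position,
                                    out$strand)
    }
  }
  dup <- duplicated(out[SITE_KEY])
  if (any(dup)) abort(sprintf("duplicate position at line %d", which(dup)[1]))
  structure(out, class = c("cytosine_reports", class(tibble())))
}

genome_base <- function(genome, scaffold, position) {
  idx <- match(scaffold, names(genome))
  if (anyNA(idx)) abort("scaffold not present in genome")
  vapply(seq_along(scaffold), function(i) {
    as.character(Biostrings::subseq(genome[[idx[i]]], position[i], position[i]))
  }, character(1))
}

#' Sequence context of a cytosine
#'
#' Strand-aware: on the plus strand the two bases 3' of the cytosine are read
#' left to right; on the minus strand the cytosine sits on the reverse
#' complement, so its context is read right to left and complemented. `CpG`
#' when the next base is G, `CHG` for C-H-G, `CHH` for C-H-H (H = A, C or T),
#' and `CHN` when a needed base is N or lies beyond the scaffold end.
#'
#' @param genome A `DNAStringSet`.
#' @param scaffold,position,strand Vectors describing cytosines (the base at
#'   the position on the given strand must be a cytosine).
#' @return Character vector of contexts.
#' @export
#' @examples
#' gen <- Biostrings::DNAStringSet(c(s1 = "ACGT"))
#' assign_context(gen, "s1", 2, "+")  # "CpG"
assign_context <- function(genome, scaffold, position, strand) {
  n <- max(length(scaffold), length(position), length(strand))
  scaffold <- rep_len(scaffold, n)
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(strand, n)
  idx <- match(scaffold, names(genome))
  if (anyNA(idx)) abort("scaffold not present in genome")
  lens <- Biostrings::width(genome)[idx]
  seqs <- as.character(genome)
  base_at <- function(i, pos) {
    ok <- pos >= 1 & pos <= lens[i]
    out <- rep(NA_character_, length(i))
    out[ok] <- substring(seqs[idx[i]][ok], pos[ok], pos[ok])
    out
  }
  i <- seq_len(n)
  b0 <- base_at(i, position)
  plus <- strand == "+"
  expected <- ifelse(plus, "C", "G")
  if (any(b0 != expected, na.rm = TRUE) || anyNA(b0)) {
    abad <- which(is.na(b0) | b0 != expected)[1]
    abort(sprintf("no cytosine on strand %s at %s:%d (base %s)",
                  strand[abad], scaffold[abad], position[abad],
                  b0[abad] %||% "NA"))
  }
  n1 <- ifelse(plus, base_at(i, position + 1L),
               unname(COMPLEMENT[base_at(i, position - 1L)]))
  n2 <- ifelse(plus, base_at(i, position + 2L),
               unname(COMPLEMENT[base_at(i, position - 2L)]))
  context_from_next(n1, n2)
}

#' Methylation calling with a minimum-coverage filter
#'
#' Drops sites whose total coverage is below `min_coverage` (the study used
#' 10) and computes the per-site methylation fraction exactly as methylated /
#' coverage.
#'
#' @param report A `cytosine_reports` tibble (single- or multi-sample).
#' @param min_coverage Minimum total reads per site (default 10).
#' @return A tibble (class `methylation_calls`): input columns plus
#'   `coverage` and `fraction`.
#' @export
call_methylation <- function(report, min_coverage = 10) {
  assert_that(min_coverage >= 1, "min_coverage must be >= 1")
  out <- report |>
    mutate(coverage = .data$count_methylated + .data$count_unmethylated) |>
    filter(.data$coverage >= min_coverage) |>
    mutate(fraction = .data$count_methylated / .data$coverage)
  attr(out, "min_coverage") <- min_coverage
  structure(out, class = c("methylation_calls", class(tibble())))
}

#' Merge symmetric CpG dyads (destranding)
#'
#' Sums the counts of the plus-strand CpG and the minus-strand CpG one base
#' downstream into a single plus-strand record. Off by default throughout the
#' pipeline; offered for comparison with destranded workflows.
#'
#' @param report A `cytosine_reports` tibble.
#' @return A `cytosine_reports` tibble with merged CpG dyads (non-CpG rows
#'   are kept untouched).
#' @export
destrand_cpgs <- function(report) {
  cpg <- filter(report, .data$context == "CpG")
  rest <- filter(report, .data$context != "CpG")
  merged <- cpg |>
    mutate(dyad = if_else(.data$strand == "+", .data$position,
                          .data$position - 1L)) |>
    group_by(.data$sample_id, .data$scaffold, .data$dyad, .data$context) |>
    summarise(
      count_methylated = sum(.data$count_methylated),
      count_unmethylated = sum(.data$count_unmethylated),
      trinucleotide = dplyr::coalesce(
        .data$trinucleotide[which(.data$strand == "+")[1]],
        .data$trinucleotide[1]),
      .groups = "drop"
    ) |>
    mutate(position = .data$dyad, strand = "+") |>
    select("sample_id", "scaffold", "position", "strand", "context",
           "trinucleotide", "count_methylated", "count_unmethylated")
  structure(bind_rows(merged, rest), class = class(report))
}

#' Unite positions covered in every sample
#'
#' methylKit-style union step: keeps positions (restricted to
#' `context_filter` if given) that pass the coverage filter in all supplied
#' samples, and lays per-sample methylated/unmethylated counts out in wide
#' columns `M_<sample>` / `U_<sample>`. Column order follows the input sample
#' order.
#'
#' @param callsets A `methylation_calls` tibble covering several samples, or
#'   a list of single-sample call sets.
#' @param context_filter Optional context (e.g. `"CpG"`).
#' @return A tibble (class `united_matrix`) with site key columns, `context`,
#'   and the per-sample count columns; the sample order is in
#'   `attr(, "samples")`.
#' @export
unite_positions <- function(callsets, context_filter = NULL) {
  has_empty_input <- FALSE
  if (is.list(callsets) && !is.data.frame(callsets)) {
    assert_that(length(callsets) >= 2, "need at least 2 samples to unite")
    has_empty_input <- any(vapply(callsets, nrow, integer(1)) == 0)
    callsets <- bind_rows(callsets)
  }
  samples <- unique(callsets$sample_id)
  if (has_empty_input) {
    # a sample with no covered positions forces an empty intersection
    out <- callsets[0, c("scaffold", "position", "strand", "context")]
    for (s in samples) {
      out[[paste0("M_", s)]] <- integer()
      out[[paste0("U_", s)]] <- integer()
    }
    attr(out, "samples") <- samples
    return(structure(out, class = c("united_matrix", class(tibble()))))
  }
  assert_that(length(samples) >= 2, "need at least 2 samples to unite")
  dups <- callsets |>
    count(.data$sample_id, .data$scaffold, .data$position, .data$strand) |>
    filter(.data$n > 1)
  if (nrow(dups)) abort("duplicate sample_id/position rows in callsets")
  d <- callsets
  if (!is.null(context_filter)) d <- filter(d, .data$context %in% context_filter)
  wide <- d |>
    group_by(.data$scaffold, .data$position, .data$strand, .data$context) |>
    filter(n() == length(samples)) |>
    ungroup() |>
    select("scaffold", "position", "strand", "context", "sample_id",
           "count_methylated", "count_unmethylated") |>
    pivot_wider(names_from = "sample_id",
                values_from = c("count_methylated", "count_unmethylated"),
                names_glue = "{ifelse(.value == 'count_methylated', 'M', 'U')}_{sample_id}") |>
    arrange(.data$scaffold, .data$position, .data$strand)
  cols <- c("scaffold", "position", "strand", "context",
            paste0("M_", samples), paste0("U_", samples))
  wide <- wide[, cols]
  attr(wide, "samples") <- samples
  structure(wide, class = c("united_matrix", class(tibble())))
}

# per-sample count matrices from a united matrix
united_counts <- function(united, samples = NULL) {
  samples <- samples %||% attr(united, "samples")
  M <- as.matrix(united[, paste0("M_", samples), drop = FALSE])
  U <- as.matrix(united[, paste0("U_", samples), drop = FALSE])
  colnames(M) <- colnames(U) <- samples
  list(M = M, U = U)
}

#' Per-context global methylation summary
#'
#' For each context present, reports both the pooled rate (sum of methylated
#' reads over sum of all reads) and the mean of per-site fractions.
#'
#' @param callset A `methylation_calls` tibble.
#' @return A tibble with `context`, `n_sites`, `pooled_rate`,
#'   `mean_fraction`.
#' @export
global_methylation_summary <- function(callset) {
  assert_that(nrow(callset) > 0, "empty call set")
  callset |>
    group_by(.data$context) |>
    summarise(
      n_sites = n(),
      pooled_rate = sum(.data$count_methylated) /
        sum(.data$count_methylated + .data$count_unmethylated),
      mean_fraction = mean(.data$fraction),
      .groups = "drop"
    )
}

#' Write methylation calls as TSV with a header
#' @param calls A `methylation_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(calls, path) {
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}
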