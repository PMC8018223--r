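# Fixture builders shared across test files.

tiny_cfg <- function(...) {
  synthetic_config(n_scaffolds = 1, scaffold_length = 20000, n_genes = 8,
                   gene_length_range = c(800, 1500), seed = 7, ...)
}

# Hand-built methylation call set: one row per (sample, site) from vectors.
make_calls <- function(sample_id, scaffold, position, strand, context,
                       count_m, count_u) {
  d <- tibble::tibble(
    sample_id = sample_id, scaffold = scaffold, position = position,
    strand = strand, context = context,
    trinucleotide = as.character(ifelse(context == "CpG", "CGA", "CAA")),
    count_methylated = count_m, count_unmethylated = count_u,
    coverage = count_m + count_u,
    fraction = ifelse(count_m + count_u > 0, count_m / (count_m + count_u), NA)
  )
  structure(d, class = c("methylation_calls", class(tibble::tibble())))
}

# Uniform-fraction CpG call set over regularly spaced sites on one scaffold.
uniform_calls <- function(fraction = 0.2, n_sites = 400, spacing = 25,
                          scaffold = "scf01", coverage = 20) {
  pos <- seq(1000, by = spacing, length.out = n_sites)
  m <- as.integer(round(fraction * coverage))
  make_calls("s1", scaffold, pos, "+", "CpG", m, coverage - m)
}

# Build a united_matrix directly from per-group count matrices.
make_united <- function(M_a, U_a, M_b, U_b,
                        samples_a = paste0("A", seq_len(ncol(M_a))),
                        samples_b = paste0("B", seq_len(ncol(M_b)))) {
  n <- nrow(M_a)
  out <- tibble::tibble(
    scaffold = "scf01", position = seq_len(n) * 10L, strand = "+",
    context = "CpG"
  )
  for (j in seq_along(samples_a)) out[[paste0("M_", samples_a[j])]] <- M_a[, j]
  for (j in seq_along(samples_b)) out[[paste0("M_", samples_b[j])]] <- M_b[, j]
  for (j in seq_along(samples_a)) out[[paste0("U_", samples_a[j])]] <- U_a[, j]
  for (j in seq_along(samples_b)) out[[paste0("U_", samples_b[j])]] <- U_b[, j]
  attr(out, "samples") <- c(samples_a, samples_b)
  structure(out, class = c("united_matrix", class(tibble::tibble())))
}

# Simulated united matrix with planted differential sites in group A.
# Coverage is negative binomial conditioned on the min-coverage filter, as a
# united matrix requires.
simulate_united <- function(n_sites, n_planted, base = 0.3, delta = 0.3,
                            cov_mu = 30, k = 3, min_cov = 10, seed = 1) {
  withr::with_seed(seed, {
    draw_cov <- function() {
      cov <- matrix(stats::rnbinom(n_sites * k, mu = cov_mu, size = 5),
                    n_sites, k)
      while (any(cov < min_cov)) {
        idx <- cov < min_cov
        cov[idx] <- stats::rnbinom(sum(idx), mu = cov_mu, size = 5)
      }
      cov
    }
    p_a <- c(rep(base + delta, n_planted), rep(base, n_sites - n_planted))
    cov_a <- draw_cov(); cov_b <- draw_cov()
    M_a <- matrix(stats::rbinom(n_sites * k, cov_a, p_a), n_sites, k)
    M_b <- matrix(stats::rbinom(n_sites * k, cov_b, base), n_sites, k)
    list(united = make_united(M_a, cov_a - M_a, M_b, cov_b - M_b),
         planted = seq_len(n_planted))
  })
}

# Two genes (one per strand) on a bare scaffold, for profile/GBMR tests.
flat_genes <- function() {
  g <- tibble::tibble(
    gene_id = c("gA", "gB"), scaffold = "scf01",
    start = c(5000L, 20000L), end = c(8000L, 24000L),
    strand = c("+", "-")
  ) |>
    dplyr::mutate(length = end - start + 1L,
                  tss = ifelse(strand == "+", start, end),
                  tes = ifelse(strand == "+", end, start))
  structure(g, class = c("gene_set", class(tibble::tibble())))
}

solid_image <- function(h, s, v, height = 4, width = 4) {
  rgb <- t(grDevices::col2rgb(grDevices::hsv((h %% 360) / 360, s, v))) / 255
  array(rep(rgb, each = height * width), dim = c(height, width, 3))
}
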