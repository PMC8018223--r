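test_that("a uniform methylome gives a flat metagene profile", {
  calls <- uniform_calls(fraction = 0.2, n_sites = 1500, spacing = 20)
  prof <- metagene_profile(calls, flat_genes())
  expect_true(all(abs(prof$mean_fraction - 0.2) < 1e-12))
  expect_setequal(unique(prof$region), c("upstream", "body", "downstream"))
})

test_that("the metagene profile is translation-equivariant", {
  calls <- uniform_calls(fraction = 0.3, n_sites = 800, spacing = 30)
  genes <- flat_genes()
  shift <- 1000L
  calls2 <- dplyr::mutate(calls, position = position + shift)
  genes2 <- dplyr::mutate(genes, start = start + shift, end = end + shift,
                          tss = tss + shift, tes = tes + shift)
  expect_equal(metagene_profile(calls, genes),
               metagene_profile(calls2, genes2), ignore_attr = TRUE)
})

test_that("a minus-strand gradient mirrors the plus-strand profile", {
  # one gene per configuration, same physical gradient rising with coordinate
  mk_gene <- function(strand) {
    g <- tibble::tibble(gene_id = "g", scaffold = "scf01", start = 10000L,
                        end = 12999L, strand = strand, length = 3000L)
    g$tss <- if (strand == "+") g$start else g$end
    g$tes <- if (strand == "+") g$end else g$start
    structure(g, class = c("gene_set", class(tibble::tibble())))
  }
  pos <- seq(7000L, 16000L, by = 10L)
  frac <- (pos - min(pos)) / diff(range(pos))  # rises left to right
  calls <- make_calls("s", "scf01", pos, "+", "CpG",
                      as.integer(round(frac * 100)),
                      as.integer(100 - round(frac * 100)))
  p_plus <- metagene_profile(calls, mk_gene("+"))
  p_minus <- metagene_profile(calls, mk_gene("-"))
  # reversing transcription direction reverses the profile
  expect_equal(p_plus$mean_fraction, rev(p_minus$mean_fraction),
               tolerance = 1e-10)
})

test_that("genic enrichment shows up as body bins above flank bins", {
  cfg <- synthetic_config(n_scaffolds = 2, scaffold_length = 40000,
                          n_genes = 12, gene_length_range = c(1500, 2500),
                          seed = 51)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)
  calls <- call_methylation(
    simulate_counts(meth, sample_design()[1, ], cfg), 10) |>
    dplyr::filter(context == "CpG")
  prof <- metagene_profile(calls, genes)
  expect_gt(mean(prof$mean_fraction[prof$region == "body"]),
            mean(prof$mean_fraction[prof$region != "body"]))
})

test_that("GBMR matches the examples and the brute-force oracle", {
  genes <- flat_genes()
  calls <- make_calls("s", "scf01", c(5100L, 5200L, 30000L), "+", "CpG",
                      c(1L, 3L, 5L), c(9L, 7L, 5L))
  g <- gene_body_methylation(calls, genes)
  expect_equal(g$gbmr[g$gene_id == "gA"], 0.2)  # mean of 0.1, 0.3
  expect_true(is.na(g$gbmr[g$gene_id == "gB"]))

  cfg <- synthetic_config(n_scaffolds = 2, scaffold_length = 60000,
                          n_genes = 50, gene_length_range = c(800, 1500),
                          seed = 53)
  genome <- generate_genome(cfg)
  genes50 <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes50, cfg)
  calls50 <- call_methylation(
    simulate_counts(meth, sample_design()[1, ], cfg), 10) |>
    dplyr::filter(context == "CpG")
  got <- gene_body_methylation(calls50, genes50)
  sites <- calls50 |>
    dplyr::group_by(scaffold, position) |>
    dplyr::summarise(fraction = mean(fraction), .groups = "drop")
  expect_equal(got$gbmr, gbmr_oracle(sites, genes50))
  # every GBMR lies within the range of its member site fractions
  rng <- range(sites$fraction)
  ok <- !is.na(got$gbmr)
  expect_true(all(got$gbmr[ok] >= rng[1] & got$gbmr[ok] <= rng[2]))
})

test_that("rank classification follows the cuts and their tie rules", {
  gm <- structure(
    tibble::tibble(gene_id = sprintf("g%02d", 1:10), n_sites = 5L,
                   gbmr = seq(0.01, 0.10, by = 0.01)),
    class = c("gene_methylation", class(tibble::tibble())))
  cl <- classify_genes_by_rank(gm)
  expect_equal(as.integer(table(cl$meth_class)[c("low", "mid", "high")]),
               c(2L, 3L, 5L))

  # invariance under strictly monotone transforms of GBMR
  gm2 <- dplyr::mutate(gm, gbmr = gbmr^3 * 7)
  expect_equal(classify_genes_by_rank(gm2)$meth_class, cl$meth_class)

  # boundary ties get average ranks, deterministically
  gmt <- dplyr::mutate(gm, gbmr = c(0.01, 0.02, 0.02, 0.02,
                                    seq(0.05, 0.10, by = 0.01)))
  c1 <- classify_genes_by_rank(gmt)
  c2 <- classify_genes_by_rank(gmt[sample(1:10), ]) |>
    dplyr::arrange(gene_id)
  expect_equal(c1$meth_class, c2$meth_class)
  expect_equal(c1$rank_fraction[2:4], rep(2 / 9, 3))  # ranks (2+3+4)/3

  expect_warning(
    all_mid <- classify_genes_by_rank(dplyr::mutate(gm, gbmr = 0.5)),
    "tied")
  expect_true(all(all_mid$meth_class == "mid"))
})

test_that("rpkm follows its definition", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), 5)  # doubling the library halves it
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 1000, 0), "positive")
})

test_that("the expression-rank curve peaks in the moderate band under hump
           coupling", {
  cfg <- synthetic_config(n_scaffolds = 2, scaffold_length = 50000,
                          n_genes = 60, gene_length_range = c(800, 1200),
                          seed = 55)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)
  classes <- attr(meth, "gene_classes")
  calls <- call_methylation(
    simulate_counts(meth, sample_design()[1, ], cfg), 10) |>
    dplyr::filter(context == "CpG")
  gm <- gene_body_methylation(calls, genes)
  expr <- simulate_expression(genes, classes, coupling = "hump", seed = 56)
  curve <- methylation_by_expression_rank(gm, expr)
  bands <- curve[curve$bin_type == "rpkm_band", ]
  mid <- bands$mean_gbmr[bands$band == "100-1000"]
  expect_gt(mid, max(bands$mean_gbmr[bands$band != "100-1000"]))

  single <- methylation_by_expression_rank(gm, expr, n_bins = 1)
  grand <- mean(gm$gbmr[gm$gene_id %in% expr$gene_id & !is.na(gm$gbmr)])
  expect_equal(single$mean_gbmr[single$bin_type == "rank"], grand)
})

test_that("clustering separates clear groups and matches the Ward oracle", {
  set.seed(61)
  n <- 200
  # two distinct site-level patterns: correlation distance sees shape, not
  # offsets, so each group follows its own pattern
  base_a <- runif(n, 0.05, 0.6)
  base_b <- runif(n, 0.05, 0.6)
  mk <- function(base, id) {
    m <- rbinom(n, 50, base)
    make_calls(id, "scf01", seq_len(n) * 10L, "+", "CpG", m, 50L - m)
  }
  calls <- dplyr::bind_rows(mk(base_a, "a1"), mk(base_a, "a2"),
                            mk(base_b, "b1"), mk(base_b, "b2"))
  u <- unite_positions(calls)
  hc <- cluster_samples(u)
  grp <- cutree(hc, 2)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_false(grp[["a1"]] == grp[["b1"]])

  # merge heights equal a brute-force Lance-Williams agglomeration
  cc <- mosaicmeth:::united_counts(u)
  frac <- cc$M / (cc$M + cc$U)
  d <- as.dist(1 - cor(frac))
  expect_equal(hc$height, ward_oracle_heights(d), tolerance = 1e-12)

  # invariant to sample input order (labels sorted internally)
  set.seed(61)
  base_a <- runif(n, 0.05, 0.6)
  base_b <- runif(n, 0.05, 0.6)
  c1 <- mk(base_a, "a1"); c2 <- mk(base_a, "a2")
  c3 <- mk(base_b, "b1"); c4 <- mk(base_b, "b2")
  hc2 <- cluster_samples(unite_positions(dplyr::bind_rows(c3, c1, c4, c2)))
  expect_equal(hc2$height, hc$height)
  expect_equal(hc2$labels, hc$labels)

  # a constant sample has no defined correlation
  const <- make_calls("c0", "scf01", seq_len(n) * 10L, "+", "CpG", 25L, 25L)
  expect_error(cluster_samples(unite_positions(
    dplyr::bind_rows(mk(base_a, "a1"), mk(base_b, "a2"), const))), "c0")

  # Newick serialization keeps all leaves
  nwk <- cluster_newick(hc)
  expect_true(all(vapply(c("a1", "a2", "b1", "b2"), grepl, logical(1),
                         x = nwk, fixed = TRUE)))
})
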