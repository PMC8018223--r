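test_that("genome generation is deterministic and honours size and GC", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 10000, seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_equal(as.character(g1), as.character(g2))
  expect_equal(Biostrings::width(g1), 10000L)

  cfg2 <- synthetic_config(n_scaffolds = 1, scaffold_length = 100000,
                           gc = 0.5, seed = 3)
  g <- generate_genome(cfg2)
  counts <- Biostrings::alphabetFrequency(g)[1, c("C", "G")]
  gc_obs <- sum(counts) / 100000
  sd3 <- 3 * sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(gc_obs - 0.5), sd3)
})

test_that("degenerate genome configurations are rejected", {
  expect_error(synthetic_config(n_scaffolds = 0), "n_scaffolds")
  expect_error(synthetic_config(scaffold_length = 500), "scaffold_length")
})

test_that("gene models are disjoint, in bounds, with strand-aware TSS", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 100000,
                          n_genes = 10, gene_length_range = c(2000, 4000),
                          seed = 5)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  expect_equal(nrow(genes), 10)
  expect_true(all(genes$start >= 1 & genes$end <= 100000))
  ord <- order(genes$start)
  expect_true(all(genes$start[ord][-1] > genes$end[ord][-10]))
  minus <- genes$strand == "-"
  expect_true(all(genes$tss[minus] > genes$tes[minus]))
  plus <- !minus
  expect_true(all(genes$tss[plus] < genes$tes[plus]))
})

test_that("infeasible gene packing is a configuration error", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 100000,
                          n_genes = 1000, gene_length_range = c(5000, 5000),
                          seed = 1)
  genome <- generate_genome(cfg)
  expect_error(generate_gene_models(genome, cfg), "cannot place")
})

test_that("gene model files round-trip through GFF3 and BED", {
  cfg <- tiny_cfg()
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_models_gff3(genes, gff)
  write_gene_models_bed(genes, bed)
  for (got in list(read_gene_models(gff, "gff3"),
                   read_gene_models(bed, "bed"))) {
    expect_equal(got$gene_id, genes$gene_id)
    expect_equal(got$start, as.integer(genes$start))
    expect_equal(got$end, as.integer(genes$end))
    expect_equal(got$strand, genes$strand)
  }
})

test_that("methylome levels follow gene class, with a bimodal gap", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 50000,
                          n_genes = 20, gene_length_range = c(1000, 2000),
                          seed = 11)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)

  # context must agree with the genome sequence at every site
  idx <- seq(1, nrow(meth), by = 97)
  expect_equal(meth$context[idx],
               assign_context(genome, meth$scaffold[idx],
                              meth$position[idx], meth$strand[idx]))
  # every cytosine exactly once per strand
  expect_false(any(duplicated(meth[c("scaffold", "position", "strand")])))

  # CHH sites carry the configured background regardless of gene class
  expect_true(all(meth$level[meth$context == "CHH"] == cfg$chh_level))

  # per-gene mean CpG level: two modes, nothing in the (low max, high min) gap
  genic <- meth[meth$context == "CpG" & !is.na(meth$gene_id), ]
  per_gene <- tapply(genic$level, genic$gene_id, mean)
  expect_false(any(per_gene > cfg$low_level_range[2] &
                     per_gene < cfg$high_level_range[1]))
  expect_true(any(per_gene <= cfg$low_level_range[2]))
  expect_true(any(per_gene >= cfg$high_level_range[1]))
})

test_that("an all-high degenerate range gives every genic CpG that level", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 30000,
                          n_genes = 6, gene_length_range = c(1000, 2000),
                          low_gene_fraction = 0, high_gene_fraction = 1,
                          high_level_range = c(0.2, 0.2), seed = 2)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)
  genic <- meth[meth$context == "CpG" & !is.na(meth$gene_id), ]
  expect_true(all(genic$level == 0.2))
})

test_that("plant_dmcs records truth, clips at the boundary, rejects excess", {
  cfg <- tiny_cfg()
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)

  planted <- plant_dmcs(meth, n_sites = 5, delta_points = 30, seed = 1)
  truth <- planted_truth(planted)
  expect_equal(nrow(truth), 5)
  expect_equal(truth$planted_level, pmin(1, truth$base_level + 0.3))
  expect_true(all(truth$affected_group == "T"))

  # clipping: a near-100-point shift on a highly methylated gene must clip
  classes <- attr(meth, "gene_classes")
  high_gene <- classes$gene_id[classes$gene_class == "high"][1]
  clipped <- expect_warning(
    plant_dmcs(meth, n_sites = 2, delta_points = 99.6,
               target_gene_ids = high_gene, seed = 2),
    "clipped"
  )
  expect_true(all(planted_truth(clipped)$clipped))
  expect_true(all(planted_truth(clipped)$planted_level == 1))

  n_avail <- sum(meth$context == "CpG" & !is.na(meth$gene_id))
  expect_error(plant_dmcs(meth, n_sites = n_avail + 1, delta_points = 30),
               "available")
})

test_that("simulated counts match the binomial model and the design", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 20000,
                          n_genes = 0, intergenic_level = 0.5,
                          conversion_error = 0, genotype_sd = 0,
                          coverage_mean = 50, seed = 4)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)
  design <- sample_design()[1, ]
  rep <- simulate_counts(meth, design, cfg)

  expect_setequal(unique(rep$sample_id), design$sample_id)
  # zero-coverage sites stay present with 0/0 counts
  expect_true(all(rep$count_methylated >= 0 & rep$count_unmethylated >= 0))

  cpg <- rep[rep$context == "CpG", ]
  tot <- sum(cpg$count_methylated) + sum(cpg$count_unmethylated)
  frac <- sum(cpg$count_methylated) / tot
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("conversion error surfaces as the observed background", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 30000,
                          n_genes = 0, intergenic_level = 0,
                          chg_level = 0, chh_level = 0,
                          conversion_error = 0.01, genotype_sd = 0,
                          coverage_mean = 30, seed = 6)
  genome <- generate_genome(cfg)
  meth <- assign_methylome(genome, generate_gene_models(genome, cfg), cfg)
  rep <- simulate_counts(meth, sample_design()[1, ], cfg)
  tot <- sum(rep$count_methylated) + sum(rep$count_unmethylated)
  frac <- sum(rep$count_methylated) / tot
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / tot))
})

test_that("high coverage recovers true fractions (round trip)", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 5000,
                          n_genes = 2, gene_length_range = c(800, 1000),
                          conversion_error = 0, genotype_sd = 0,
                          coverage_mean = 2e5, coverage_dispersion = 1e6,
                          seed = 8)
  genome <- generate_genome(cfg)
  meth <- assign_methylome(genome, generate_gene_models(genome, cfg), cfg)
  rep <- simulate_counts(meth, sample_design()[1, ], cfg)
  obs <- rep$count_methylated /
    (rep$count_methylated + rep$count_unmethylated)
  expect_lt(max(abs(obs - meth$level)), 0.005 + 1e-9)
})

test_that("the full factorial design and the reports are complete", {
  d <- sample_design()
  expect_equal(nrow(d), 18)
  expect_equal(nrow(dplyr::distinct(d, genotype, treatment, time)), 18)
  expect_false(anyDuplicated(d$sample_id) > 0)

  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 2000,
                          n_genes = 0, seed = 9)
  genome <- generate_genome(cfg)
  meth <- assign_methylome(genome, generate_gene_models(genome, cfg), cfg)
  rep <- simulate_counts(meth, d, cfg)
  expect_equal(sort(unique(rep$sample_id)), sort(d$sample_id))
})

test_that("identical config and seed give byte-identical report files", {
  cfg <- synthetic_config(n_scaffolds = 1, scaffold_length = 3000,
                          n_genes = 2, gene_length_range = c(500, 800),
                          seed = 10)
  gen_once <- function(dir) {
    genome <- generate_genome(cfg)
    meth <- assign_methylome(genome, generate_gene_models(genome, cfg), cfg)
    rep <- simulate_counts(meth, sample_design()[1:2, ], cfg)
    write_cytosine_reports(rep, dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- gen_once(d1); p2 <- gen_once(d2)
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("expression coupling produces (only) the intended hump", {
  cfg <- synthetic_config(n_scaffolds = 2, scaffold_length = 50000,
                          n_genes = 60, gene_length_range = c(800, 1200),
                          seed = 12)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  meth <- assign_methylome(genome, genes, cfg)
  classes <- attr(meth, "gene_classes")

  hump <- simulate_expression(genes, classes, coupling = "hump", seed = 1)
  d <- dplyr::inner_join(hump, classes, by = "gene_id")
  band <- cut(d$rpkm, c(-Inf, 100, 1000, Inf),
              labels = c("lo", "mid", "hi"))
  mid_m <- mean(d$gene_level[band == "mid"])
  expect_gt(mid_m, mean(d$gene_level[band == "lo"]))
  expect_gt(mid_m, mean(d$gene_level[band == "hi"]))

  # with no coupling, class and expression band are independent
  classes_big <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    gene_class = rep(c("low", "high"), 500), gene_level = 0
  )
  genes_big <- tibble::tibble(gene_id = classes_big$gene_id)
  none <- simulate_expression(genes_big, classes_big, coupling = "none",
                              seed = 2)
  band2 <- cut(none$rpkm, c(-Inf, 100, 1000, Inf))
  tab <- table(classes_big$gene_class, band2)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.05)

  empty <- simulate_expression(genes[0, ], classes[0, ], seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("shell image generation is exact without noise and deterministic", {
  imgs <- generate_shell_images(2, base_hsv = c(30, 0.5, 0.7),
                                darkness_shift = 0, noise_sd = 0, seed = 1)
  px <- imgs$image[[1]]
  expect_equal(dim(px), c(32, 32, 3))
  expect_equal(max(abs(sweep(px, 3, px[1, 1, ]))), 0)

  base <- hsb_stats(imgs$image[[1]])
  shifted <- generate_shell_images(1, base_hsv = c(30, 0.5, 0.7),
                                   darkness_shift = 0.3, noise_sd = 0,
                                   seed = 1)
  dark <- hsb_stats(shifted$image[[1]])
  expect_equal(dark$darkness - base$darkness, 0.3, tolerance = 0.01)

  a <- generate_shell_images(10, noise_sd = 0.05, seed = 42)
  b <- generate_shell_images(10, noise_sd = 0.05, seed = 42)
  expect_identical(a$image, b$image)
})

test_that("images survive a PNG round trip", {
  imgs <- generate_shell_images(2, noise_sd = 0.05, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_shell_images(imgs, dir)
  back <- read_shell_image(paths[1])
  expect_equal(back, imgs$image[[1]], tolerance = 1 / 255)
})
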