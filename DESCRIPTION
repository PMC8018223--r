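Package: mosaicmeth
Title: Differential DNA Methylation Analysis for Mosaic Invertebrate Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for whole-genome bisulfite sequencing
    analysis of mosaic (invertebrate-type) methylomes, built around a
    depth-variation ("yo-yo") experiment on the pearl oyster mantle. Provides
    parsers for Bismark per-cytosine count files, minimum-coverage methylation
    calling, per-site differential methylation testing (binomial logistic
    regression with a Fisher exact fallback, Benjamini-Hochberg adjustment,
    methylation-difference filter), a nine-comparison design that disentangles
    time, depth-plus-time and depth-plus-genotype effects including the
    time-effect subtraction, methylome characterization (metagene profiles,
    gene-body methylation rates, bimodal low/high gene classification,
    expression-rank curves, Ward clustering on correlation distance),
    Fisher-exact GO term enrichment, HSV-based shell color phenotyping with
    exact Wilcoxon tests, and a fully deterministic synthetic-data generator
    that emulates the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    grDevices,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
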