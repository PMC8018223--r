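---
title: "Methods: depth-responsive DNA methylation in a mosaic methylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-responsive DNA methylation in a mosaic methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicmeth)
library(dplyr)
```

## The question and the design

Pearl oysters moved from 8 m to 30 m depth darken their inner shell, and
the darkening persists after they return to 8 m — an enduring,
environmentally induced phenotype that suggests epigenetic control rather
than a direct physiological response. The analysis this package implements
asks whether whole-genome bisulfite sequencing of the mantle (the
biomineralizing tissue) shows methylation changes that track the depth
treatment, while holding genotype constant.

The "yo-yo" design crosses three genotypes (families) with two treatments
and three monthly sampling times: three control individuals stay at 8 m
throughout; three treatment individuals go 8 m → 30 m → 8 m; each animal is
sampled non-lethally at every transfer. That gives 18 samples
(`sample_design()`), and — because the same genotypes appear in both groups
and at all times — three families of pairwise comparisons that disentangle
the confounded effects:

* **time**: C-S1 vs C-S2, C-S2 vs C-S3, C-S1 vs C-S3 (seasonal drift only);
* **depth + time**: the same contrasts among treatment individuals;
* **depth + genotype**: T vs C at each sampling time.

Sites differentially methylated across time among the controls are judged
non-significant in the treatment-across-time family:
`depth_only = depth_time ∖ time`, subtracted by genomic position
regardless of direction (a conservative reading — a position that moves
with time in *either* direction is discounted). The depth+genotype family
is reported but takes no part in the subtraction, since it confounds the
treatment with between-individual differences. Non-redundant unions within
a family are keyed by (site, direction), so hyper- and hypomethylation
counts can be reported separately; a site discordant between comparisons
keeps both entries and a flag rather than being silently resolved.

## The statistical model at each site

Counts enter as per-cytosine (methylated, unmethylated) pairs per sample.
After a strict minimum-coverage filter (default 10 reads, the value used
throughout) and uniting of positions covered in every sample of a
comparison, each site is tested for a group difference:

* With replicates in both groups, a binomial logistic regression of the
  methylated proportion on the group indicator, tested against the
  intercept-only model by likelihood ratio (1 df). With a single binary
  covariate the group MLEs are the pooled group proportions, so the LRT
  statistic has a closed form in the pooled counts; the implementation uses
  that form (it is algebraically identical to `glm()` + LRT, and the test
  suite verifies the equality) and applies no overdispersion correction.
  When a group's pooled proportion is exactly 0 or 1 the group coefficient
  is unbounded (separation); those sites fall back to Fisher's exact test
  on pooled counts and are flagged.
* Without replicates, the two-sided Fisher exact test: the sum of
  hypergeometric probabilities not exceeding that of the observed table.
  Degenerate margins give p = 1.

q-values are Benjamini–Hochberg within one comparison (the FDR family is
the sites of that comparison, not the nine comparisons jointly). A site is
a differentially methylated cytosine (DMC) when `|Δ| > 25` percentage
points **and** `q < 0.05`, both strict, with Δ the pooled
(coverage-weighted) percent difference; an unweighted mean-of-fractions
difference is available by option. BH was chosen over methylKit's SLIM
q-values: SLIM is nonstandard to reproduce exactly, while BH is the
transparent, widely understood default — a deliberate, documented
substitution.

With triplicates at coverage ~30 the pooled group coverage is ~90 reads,
so the sampling SD of Δ for a site shifted by 30 points is ~6–7 points and
the strict 25-point filter passes roughly 75–80% of truly shifted sites;
recovering more than ~80% of 30-point effects needs pooled coverage around
130 per group (per-sample coverage ≳ 42 with triplicates). This is worth
keeping in mind when sizing an experiment against the filter.

## Methylome characterization

* **Metagene profile**: deepTools-style scale-regions — each gene body is
  rescaled to 60 bins and the 3-kb flanks are cut into 30 fixed 100-bp bins,
  strand-aware. Site fractions are averaged within each gene's bins first,
  then across genes, so long genes do not dominate. Body bins use midpoint
  binning (`floor((d + 0.5)/len · 60)`) and flank bins 1-based distances
  from the gene edge; both choices make the layout exactly symmetric under
  strand reversal, which the tests exercise with mirrored gradients.
* **GBMR**: the gene body methylation rate is the unweighted mean of
  per-site CpG fractions over the annotated gene span (bedtools
  `map -o mean` semantics; introns included), not coverage-weighted. Genes
  without covered CpGs are excluded from ranking.
* **Classification**: the bimodal GBMR distribution is split by fractional
  rank, `(rank − 1)/(n − 1)` with average ranks for ties: ≤ 0.2 is "low",
  ≥ 0.5 is "high", in between is "mid" and excluded from enrichment
  contrasts. Rank is the operative rule (the printed methylation ranges of
  any one data set are data-dependent), so the classes are invariant under
  any strictly monotone transform of GBMR. Ten strictly increasing genes
  split 2/3/5. An all-tied input classifies everything "mid" with a
  warning.
* **Expression**: RPKM = `1e9 · counts / (length_bp · library_size)`; the
  methylation-by-expression curve reports equal-size expression-rank bins
  plus the three fixed bands < 100, 100–1000, > 1000 RPKM. The moderate
  band showing the highest gene-body methylation is the expected
  invertebrate pattern.
* **Clustering**: Ward agglomeration (`hclust(method = "ward.D")`) on
  `1 − Pearson` distance between per-sample fraction profiles, the
  methylKit convention. Samples are sorted by label first so input order
  cannot change the tree; a constant sample (undefined correlation) is an
  error naming the sample.

## GO enrichment

DMCs are assigned to gene bodies inclusively at both ends and
strand-agnostically; intergenic DMCs are discarded and counted; a DMC under
two overlapping genes counts for both, flagged. Term enrichment is the
one-sided (greater) Fisher exact test — the upper hypergeometric tail of
the 2×2 study/rest × term/no-term table — for every term with at least one
study gene, with BH within each namespace (BP and MF are separate
families). No ancestor propagation is applied: terms are tested as
annotated, matching a term map supplied as a plain two-column table.

## Color phenotyping

Each shell image is summarized in HSV: mean saturation, darkness defined
operationally as 1 − mean brightness (value channel), and the circular mean
hue (unit-vector averaging, so hues 350° and 10° average to 0°, not 180°).
Shapiro–Wilk (Royston's approximation, via `stats`) describes normality per
group; group contrasts use the two-sided Wilcoxon rank-sum test, exact by
enumeration when the combined sample is ≤ 25 without ties, otherwise the
tie-corrected normal approximation. Ten screenshots per sample is the
default group size; two fully separated groups of ten bottom out at
p = 2/184756 ≈ 1.08 × 10⁻⁵, the floor the exact test allows at that size.

## What the generator emulates — and what it does not

`synthetic_config()` fixes the study conditions; the generator is
deterministic given the seed (identical seeds give byte-identical files).

* **Genome and genes**: i.i.d. bases at GC 0.35 (a mollusc-like
  composition); non-overlapping genes, uniform lengths 1–3 kb, random
  strands; defaults 4 × 50 kb scaffolds, 40 genes.
* **Mosaic methylome**: 20% of genes draw a level from 0.0000–0.0019
  (the "low" mode) and 80% from 0.005–0.4012 (the "high" mode) — the two
  observed mode ranges of the bimodal gene-body distribution — leaving the
  band between 0.0019 and 0.005 empty by construction; intergenic CpGs sit
  at 0.03, CHG/CHH everywhere near 0.009/0.010, so methylation is
  CpG-dominant and gene-body-enriched.
* **Counts**: coverage is negative binomial (mean 30, size 5) rather than
  Poisson, emulating WGBS overdispersion so the minimum-coverage filter has
  real work to do; methylated counts are binomial with a symmetric
  bisulfite conversion error (default 0.005) applied as
  `p = f(1−e) + (1−f)e`. No published conversion efficiency was available,
  so the error model and its rate are stated assumptions.
* **Structure between samples**: a per-genotype, per-site Gaussian offset
  (SD 0.01) gives genotype signal to the clustering; planted DMCs shift
  selected genic CpGs by a chosen number of points only in the affected
  (treatment, time) cells, with a truth table (including clipping flags)
  for recovery scoring; default 50 sites at +30 points in T at S2 and S3 —
  above the 25-point filter, as a power test requires.
* **Phenotype**: near-uniform HSV images whose value channel drops by a
  darkness shift in the affected groups, with per-pixel Gaussian noise,
  kept in double precision so measured darkness is continuous.

Deliberately not emulated: sequence composition beyond GC content, CpG
islands, M-bias and position-dependent error, correlated errors between
neighboring sites, coverage that tracks GC, chimeric or incompletely
converted reads, real GO term hierarchies, and any real shell texture.
Passing tests therefore demonstrate the pipeline's statistical behaviour
under its own model assumptions — calibration, recovery, invariances —
not robustness to the artifacts real libraries carry into alignment-stage
tools.

## Numerical and degenerate-input choices

* Strand is kept: symmetric CpG dyads are *not* merged by default
  (`destrand_cpgs()` exists for comparison work). No coverage
  normalization between samples, no upper-percentile coverage filter.
* Coordinates are 1-based inclusive internally (Bismark convention);
  BED output is converted to 0-based half-open.
* Both DMC thresholds are strict inequalities: a site at exactly +25.0
  points, or q exactly 0.05, is not a DMC.
* Fisher ties use the conventional `(1 + 1e-7)` relative tolerance when
  summing probabilities "at most" the observed table's.
* Empty inputs: an empty count file parses to an empty report; uniting
  with a sample that has no covered positions yields an empty matrix; an
  empty study set or an all-constant Shapiro input is an error.
* Parsers fail with the offending line number rather than guessing.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances — 10 000–12 000 united CpG sites for calibration and recovery,
50–60 genes for classification, 18 samples for the full design, 200-kb
synthetic genomes — sizes chosen so the whole suite completes in about a
minute while keeping every binomial approximation comfortably in its
working range. All thresholds are identical to those a full-size run would
use.

## Known limitations

* The per-site LRT is asymptotic; at coverage well below ~10 per sample its
  calibration degrades (the united filter keeps such sites out by default).
* BH q-values differ numerically from SLIM q-values, so DMC counts are not
  expected to match SLIM-based analyses site for site.
* GBMR treats the annotated span as the gene body; exon/intron-resolved
  rates are only as good as the supplied annotation.
* Darkness is one operational definition (1 − mean V); other HSB
  statistics (median V, per-channel trims) would shift absolute values,
  though not the rank-based group tests for monotone changes.
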