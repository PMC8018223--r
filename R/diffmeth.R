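#' Pooled methylation difference in percentage points
#'
#' The coverage-weighted (pooled within group) percent difference used by the
#' DMC filter: `100 * (sum(M_A)/sum(M_A + U_A) - sum(M_B)/sum(M_B + U_B))`.
#' Vectors recycle, so site-wise vectors of pooled counts work directly.
#'
#' @param m_a,u_a Pooled methylated / unmethylated counts, group A.
#' @param m_b,u_b Pooled counts, group B.
#' @return Difference in percentage points (A minus B); `NA` where a group
#'   has zero total coverage.
#' @export
#' @examples
#' methylation_difference(24, 6, 15, 15)  # +30
methylation_difference <- function(m_a, u_a, m_b, u_b) {
  ta <- m_a + u_a
  tb <- m_b + u_b
  out <- 100 * (m_a / ta - m_b / tb)
  out[ta == 0 | tb == 0] <- NA_real_
  out
}

#' Two-sided Fisher exact test on pooled counts
#'
#' The no-replicate fallback test: for the 2x2 table
#' `rbind(c(m_a, u_a), c(m_b, u_b))` the two-sided p is the sum of
#' hypergeometric probabilities not exceeding that of the observed table
#' (with the conventional relative tolerance for ties). Degenerate margins
#' (an all-zero row or column) give p = 1.
#'
#' @inheritParams methylation_difference
#' @return Vector of p-values.
#' @export
#' @examples
#' site_test_fisher(10, 0, 0, 10)  # 2 / choose(20, 10)
site_test_fisher <- function(m_a, u_a, m_b, u_b) {
  n <- max(length(m_a), length(u_a), length(m_b), length(u_b))
  m_a <- rep_len(m_a, n); u_a <- rep_len(u_a, n)
  m_b <- rep_len(m_b, n); u_b <- rep_len(u_b, n)
  assert_that(all(c(m_a, u_a, m_b, u_b) >= 0), "counts must be non-negative")
  vapply(seq_len(n), function(i) {
    ra <- m_a[i] + u_a[i]
    rb <- m_b[i] + u_b[i]
    k <- m_a[i] + m_b[i]
    nn <- ra + rb
    if (ra == 0 || rb == 0 || k == 0 || k == nn) return(1)
    support <- max(0, k - rb):min(k, ra)
    pr <- dhyper(support, ra, rb, k)
    p_obs <- dhyper(m_a[i], ra, rb, k)
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

# closed-form binomial logistic LRT for a two-group comparison; identical to
# glm(cbind(M, U) ~ group, family = binomial) tested against the intercept
# model by likelihood ratio: with a single binary covariate the group MLEs
# are the pooled group proportions, so only pooled counts enter.
binomial_lrt <- function(m_a, u_a, m_b, u_b) {
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ta <- m_a + u_a; tb <- m_b + u_b
  pa <- m_a / ta; pb <- m_b / tb
  p0 <- (m_a + m_b) / (ta + tb)
  ll <- function(m, u, p) xlogy(m, p) + xlogy(u, 1 - p)
  g <- 2 * (ll(m_a, u_a, pa) + ll(m_b, u_b, pb) - ll(m_a, u_a, p0) -
              ll(m_b, u_b, p0))
  pchisq(pmax(g, 0), df = 1, lower.tail = FALSE)
}

#' Replicated-design site test (binomial logistic regression LRT)
#'
#' Likelihood-ratio chi-square (1 df) comparing the binomial logistic model
#' with a group indicator against the intercept-only model -- the replicated
#' stand-in for methylKit's per-site logistic regression, with no
#' overdispersion correction. When a group's pooled proportion is exactly 0
#' or 1 the group coefficient is unbounded (separation) and the test falls
#' back to the Fisher exact test on pooled counts, flagged in the output.
#'
#' @param M_a,U_a Matrices (sites x samples) of methylated / unmethylated
#'   counts for group A; vectors are treated as single-sample columns.
#' @param M_b,U_b The same for group B.
#' @return A tibble with `p` and `test` (`"glm"` or `"fisher"`).
#' @export
site_test_glm <- function(M_a, U_a, M_b, U_b) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)
  M_a <- as_m(M_a); U_a <- as_m(U_a); M_b <- as_m(M_b); U_b <- as_m(U_b)
  m_a <- rowSums(M_a); u_a <- rowSums(U_a)
  m_b <- rowSums(M_b); u_b <- rowSums(U_b)
  pa <- m_a / (m_a + u_a)
  pb <- m_b / (m_b + u_b)
  separated <- pa %in% c(0, 1) | pb %in% c(0, 1)
  p <- binomial_lrt(m_a, u_a, m_b, u_b)
  if (any(separated)) {
    p[separated] <- site_test_fisher(m_a[separated], u_a[separated],
                                     m_b[separated], u_b[separated])
  }
  tibble(p = p, test = if_else(separated, "fisher", "glm"))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; monotone in p-rank and never below the raw p.
#'
#' @param pvals Vector of p-values in \[0,1\].
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return Adjusted q-values.
#' @export
#' @examples
#' adjust_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
adjust_qvalues <- function(pvals, method = "BH") {
  assert_that(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(pvals, method = method)
}

#' Differentially methylated cytosines of one pairwise comparison
#'
#' Tests every united site (binomial-logistic LRT when both groups are
#' replicated, Fisher exact otherwise), adjusts p-values by
#' Benjamini-Hochberg across all sites of the comparison, and retains sites
#' with `|difference| > diff_threshold` percentage points and
#' `q < q_threshold` -- both strict, matching the study's filter (difference
#' > 25, q < 0.05). Sites with higher pooled methylation in group A are
#' `hyper`, lower are `hypo`.
#'
#' @param united A `united_matrix` from [unite_positions()].
#' @param group_a,group_b Character vectors of sample ids forming the two
#'   groups (A first: hyper means A above B).
#' @param diff_threshold Methylation-difference threshold in percentage
#'   points (strict).
#' @param q_threshold q-value threshold (strict).
#' @param comparison Label for the comparison (e.g. `"T-S1 vs C-S1"`).
#' @param diff_method `"pooled"` (coverage-weighted, default) or `"mean"`
#'   (unweighted mean of per-sample fractions) for the reported difference.
#' @return A `dmc_set` object: list with `comparison`, `results` (every
#'   tested site with `meth_diff`, `p`, `q`, `test`), `dmcs` (sites passing
#'   both filters, with `direction`), `n_hyper`, `n_hypo`, and the
#'   thresholds. `tidy()` returns the DMC table, `glance()` the counts.
#' @export
get_methyl_diff <- function(united, group_a, group_b,
                            diff_threshold = 25, q_threshold = 0.05,
                            comparison = "A vs B",
                            diff_method = c("pooled", "mean")) {
  diff_method <- match.arg(diff_method)
  samples <- attr(united, "samples")
  missing <- setdiff(c(group_a, group_b), samples)
  if (length(missing)) {
    abort(paste0("samples absent from united matrix: ",
                 paste(missing, collapse = ", ")))
  }
  assert_that(nrow(united) > 0, "united matrix is empty")
  ca <- united_counts(united, group_a)
  cb <- united_counts(united, group_b)
  m_a <- rowSums(ca$M); u_a <- rowSums(ca$U)
  m_b <- rowSums(cb$M); u_b <- rowSums(cb$U)

  meth_diff <- if (diff_method == "pooled") {
    methylation_difference(m_a, u_a, m_b, u_b)
  } else {
    100 * (rowMeans(ca$M / (ca$M + ca$U)) - rowMeans(cb$M / (cb$M + cb$U)))
  }

  if (length(group_a) >= 2 && length(group_b) >= 2) {
    tst <- site_test_glm(ca$M, ca$U, cb$M, cb$U)
  } else {
    tst <- tibble(p = site_test_fisher(m_a, u_a, m_b, u_b), test = "fisher")
  }

  results <- united |>
    select("scaffold", "position", "strand", "context") |>
    mutate(meth_diff = meth_diff, p = tst$p, q = adjust_qvalues(tst$p),
           test = tst$test)
  keep <- !is.na(results$meth_diff) &
    abs(results$meth_diff) > diff_threshold & results$q < q_threshold
  dmcs <- results[keep, ] |>
    mutate(direction = if_else(.data$meth_diff > 0, "hyper", "hypo"),
           comparison = comparison)
  structure(
    list(comparison = comparison, results = results, dmcs = dmcs,
         n_hyper = sum(dmcs$direction == "hyper"),
         n_hypo = sum(dmcs$direction == "hypo"),
         diff_threshold = diff_threshold, q_threshold = q_threshold,
         group_a = group_a, group_b = group_b),
    class = "dmc_set"
  )
}

#' @export
print.dmc_set <- function(x, ...) {
  cat(sprintf("<dmc_set> %s: %d sites tested, %d DMCs (%d hyper / %d hypo)\n",
              x$comparison, nrow(x$results), nrow(x$dmcs),
              x$n_hyper, x$n_hypo))
  cat(sprintf("  filter: |difference| > %g points, q < %g\n",
              x$diff_threshold, x$q_threshold))
  invisible(x)
}

#' Write a DMC set as BED6+ TSV
#'
#' Columns: scaffold, 0-based start, end, name, meth_diff, strand, p, q,
#' direction.
#'
#' @param dmc_set A `dmc_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmc_bed <- function(dmc_set, path) {
  d <- dmc_set$dmcs
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t%s\t%.6g\t%.6g\t%s",
                   d$scaffold, d$position - 1L, d$position,
                   sprintf("%s_%s_%d", dmc_set$comparison, d$scaffold,
                           d$position),
                   d$meth_diff, d$strand, d$p, d$q, d$direction)
  writeLines(lines, path)
  invisible(path)
}
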