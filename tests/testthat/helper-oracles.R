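# Independent brute-force oracles used to check the fast implementations.

# Two-sided Fisher exact p by explicit table enumeration: probabilities from
# products of binomial coefficients, independent of dhyper.
fisher_oracle <- function(m_a, u_a, m_b, u_b) {
  ra <- m_a + u_a
  rb <- m_b + u_b
  k <- m_a + m_b
  n <- ra + rb
  if (ra == 0 || rb == 0 || k == 0 || k == n) return(1)
  support <- max(0, k - rb):min(k, ra)
  pr <- vapply(support, function(x) {
    choose(ra, x) * choose(rb, k - x) / choose(n, k)
  }, numeric(1))
  p_obs <- pr[support == m_a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled values to group A.
wilcox_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  mu <- na * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Hypergeometric upper-tail enrichment p by direct summation.
enrich_oracle <- function(study_hits, study_n, pop_hits, pop_n) {
  ks <- study_hits:min(study_n, pop_hits)
  sum(vapply(ks, function(k) {
    choose(pop_hits, k) * choose(pop_n - pop_hits, study_n - k) /
      choose(pop_n, study_n)
  }, numeric(1)))
}

# Ward agglomeration (classic "ward.D" Lance-Williams update) from a distance
# matrix; returns the merge heights in order, for comparison with hclust.
ward_oracle_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bh <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        if (d[active[i], active[j]] < bh) {
          bh <- d[active[i], active[j]]
          best <- c(active[j], active[i])
        }
      }
    }
    heights <- c(heights, bh)
    i <- best[1]; j <- best[2]
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * bh) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Per-gene mean of site fractions by a double loop, bedtools-map style.
gbmr_oracle <- function(sites, genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    sel <- sites$scaffold == genes$scaffold[i] &
      sites$position >= genes$start[i] & sites$position <= genes$end[i]
    if (!any(sel)) NA_real_ else mean(sites$fraction[sel])
  }, numeric(1))
}

# Brute-force context caller by direct string matching on one sequence.
context_oracle <- function(seq_chr, position, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(seq_chr, "")[[1]]
  get <- function(p) if (p >= 1 && p <= length(ch)) ch[p] else NA_character_
  if (strand == "+") {
    n1 <- get(position + 1); n2 <- get(position + 2)
  } else {
    n1 <- unname(comp[get(position - 1)]); n2 <- unname(comp[get(position - 2)])
  }
  if (is.na(n1) || n1 == "N") return("CHN")
  if (n1 == "G") return("CpG")
  if (is.na(n2) || n2 == "N") return("CHN")
  if (n2 == "G") return("CHG") else return("CHH")
}
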