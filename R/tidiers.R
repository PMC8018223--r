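#' Tidy a DMC set
#'
#' @param x A `dmc_set`.
#' @param all_sites If `TRUE`, return every tested site rather than only the
#'   sites passing the DMC filter.
#' @param ... Unused.
#' @return A tibble of DMCs (or of all tested sites).
#' @export
tidy.dmc_set <- function(x, all_sites = FALSE, ...) {
  if (all_sites) as_tibble(x$results) else as_tibble(x$dmcs)
}

#' One-row summary of a DMC set
#' @param x A `dmc_set`.
#' @param ... Unused.
#' @return A one-row tibble with the comparison label, numbers of tested
#'   sites and DMCs, and the filter thresholds.
#' @export
glance.dmc_set <- function(x, ...) {
  tibble(comparison = x$comparison, n_tested = nrow(x$results),
         n_dmc = nrow(x$dmcs), n_hyper = x$n_hyper, n_hypo = x$n_hypo,
         diff_threshold = x$diff_threshold, q_threshold = x$q_threshold)
}

#' Tidy effect sets into one long DMC table
#' @param x An `effect_sets`.
#' @param ... Unused.
#' @return A tibble of all effect-family DMCs with a `family` column.
#' @export
tidy.effect_sets <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) mutate(x[[nm]], family = nm))
}

#' One-row summary of effect sets
#' @param x An `effect_sets`.
#' @param ... Unused.
#' @return A one-row tibble of per-family sizes.
#' @export
glance.effect_sets <- function(x, ...) {
  tibble(n_time = nrow(x$time), n_depth_time = nrow(x$depth_time),
         n_depth_genotype = nrow(x$depth_genotype),
         n_depth_only = nrow(x$depth_only))
}

#' Tidy a phenotype result (the pairwise test table)
#' @param x A `phenotype_result`.
#' @param ... Unused.
#' @return The pairwise Wilcoxon test tibble.
#' @export
tidy.phenotype_result <- function(x, ...) as_tibble(x$tests)

#' One-row summary of a phenotype result
#' @param x A `phenotype_result`.
#' @param ... Unused.
#' @return A one-row tibble: group and image counts, smallest darkness p.
#' @export
glance.phenotype_result <- function(x, ...) {
  dk <- x$tests[x$tests$channel == "darkness", ]
  tibble(n_groups = dplyr::n_distinct(x$measurements$group),
         n_images = nrow(x$measurements),
         min_darkness_p = if (nrow(dk)) min(dk$p) else NA_real_)
}
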