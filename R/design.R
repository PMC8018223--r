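#' Enumerate the nine effect-disentangling comparisons
#'
#' The yo-yo design supports three families of three pairwise comparisons:
#' \describe{
#'   \item{time}{among controls across times: C-S1 vs C-S2, C-S2 vs C-S3,
#'     C-S1 vs C-S3 (seasonal / time effect only).}
#'   \item{depth_time}{among treatment individuals across times: T-S1 vs
#'     T-S2, T-S2 vs T-S3, T-S1 vs T-S3 (depth plus time).}
#'   \item{depth_genotype}{treatment vs control at each time: T-S1 vs C-S1,
#'     T-S2 vs C-S2, T-S3 vs C-S3 (depth plus genotype).}
#' }
#' Each comparison names two groups of one sample per genotype (triplicates
#' by treatment/time cell).
#'
#' @param design A [sample_design()]; must contain the full
#'   genotypes x treatments x times factorial.
#' @return A tibble with `comparison`, `family`, and list-columns `group_a`,
#'   `group_b` of sample ids.
#' @export
enumerate_comparisons <- function(design) {
  treatments <- c("C", "T")
  times <- sprintf("S%d", 1:3)
  cells <- tidyr::expand_grid(treatment = treatments, time = times)
  have <- design |> distinct(.data$treatment, .data$time)
  missing <- anti_join(cells, have, by = c("treatment", "time"))
  if (nrow(missing)) {
    abort(paste0("design is missing cells: ",
                 paste(sprintf("%s-%s", missing$treatment, missing$time),
                       collapse = ", ")))
  }
  cell_samples <- function(tr, ti) {
    design$sample_id[design$treatment == tr & design$time == ti]
  }
  pairs <- bind_rows(
    tibble(family = "time", a_tr = "C", a_ti = c("S1", "S2", "S1"),
           b_tr = "C", b_ti = c("S2", "S3", "S3")),
    tibble(family = "depth_time", a_tr = "T", a_ti = c("S1", "S2", "S1"),
           b_tr = "T", b_ti = c("S2", "S3", "S3")),
    tibble(family = "depth_genotype", a_tr = "T", a_ti = times,
           b_tr = "C", b_ti = times)
  )
  pairs |>
    mutate(
      comparison = sprintf("%s-%s vs %s-%s", .data$a_tr, .data$a_ti,
                           .data$b_tr, .data$b_ti),
      group_a = purrr::map2(.data$a_tr, .data$a_ti, cell_samples),
      group_b = purrr::map2(.data$b_tr, .data$b_ti, cell_samples)
    ) |>
    select("comparison", "family", "group_a", "group_b")
}

#' Non-redundant union of DMC sets
#'
#' Unions DMC tables keyed by (scaffold, position, strand, direction): a site
#' recurring in several comparisons of a family counts once per direction. A
#' site reported hyper in one comparison and hypo in another keeps both
#' entries, flagged `discordant`.
#'
#' @param dmc_sets A list of `dmc_set` objects (or of their `dmcs` tibbles).
#' @return A tibble of unique (site, direction) records with `discordant`.
#' @export
nonredundant_union <- function(dmc_sets) {
  tabs <- purrr::map(dmc_sets, function(x) {
    if (inherits(x, "dmc_set")) x$dmcs else x
  })
  all <- bind_rows(tabs)
  if (nrow(all) == 0) {
    return(tibble(scaffold = character(), position = integer(),
                  strand = character(), context = character(),
                  direction = character(), discordant = logical()))
  }
  u <- all |>
    distinct(.data$scaffold, .data$position, .data$strand, .data$context,
             .data$direction)
  u |>
    group_by(.data$scaffold, .data$position, .data$strand) |>
    mutate(discordant = n_distinct(.data$direction) > 1) |>
    ungroup()
}

#' Subtract the time effect from the depth-plus-time effect
#'
#' Sites differentially methylated across time among the controls are
#' regarded as non-significant in the treatment-across-time family:
#' `depth_only = depth_time` minus any site keyed in `time`. The subtraction
#' key is the genomic site (scaffold, position, strand), regardless of
#' direction -- a position time-affected in either direction is excluded.
#'
#' @param depth_time,time Non-redundant DMC tibbles
#'   (from [nonredundant_union()]).
#' @return The depth-only DMC tibble.
#' @export
subtract_time_effect <- function(depth_time, time) {
  if (nrow(time) == 0) return(depth_time)
  anti_join(depth_time, time[SITE_KEY], by = SITE_KEY)
}

#' Compute the three effect families and the depth-only set
#'
#' Runs [nonredundant_union()] per family and [subtract_time_effect()] on
#' the result. The depth+genotype family is reported but takes no part in
#' the subtraction.
#'
#' @param dmc_sets A named list of nine `dmc_set` objects.
#' @param comparisons The comparison table from [enumerate_comparisons()]
#'   (supplies the family of each comparison; matched by name or order).
#' @return An `effect_sets` object: list with tibbles `time`, `depth_time`,
#'   `depth_genotype`, `depth_only`.
#' @export
effect_sets <- function(dmc_sets, comparisons) {
  labs <- purrr::map_chr(dmc_sets, function(x) x$comparison)
  fam <- comparisons$family[match(labs, comparisons$comparison)]
  if (anyNA(fam)) abort("dmc_sets contain comparisons not in the design")
  by_family <- split(dmc_sets, fam)
  u <- purrr::map(by_family, nonredundant_union)
  empty <- nonredundant_union(list())
  out <- list(
    time = u[["time"]] %||% empty,
    depth_time = u[["depth_time"]] %||% empty,
    depth_genotype = u[["depth_genotype"]] %||% empty
  )
  out$depth_only <- subtract_time_effect(out$depth_time, out$time)
  structure(out, class = "effect_sets")
}

#' @export
print.effect_sets <- function(x, ...) {
  cat("<effect_sets>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s %d site(s)\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Per-effect hyper/hypo counts by context
#'
#' The tabular mirror of the nine-comparison figure: counts of hyper- and
#' hypomethylated positions per effect family and sequence context.
#'
#' @param effects An `effect_sets` object.
#' @return A tibble with `family`, `context`, `direction`, `n` (zero rows
#'   for empty families are retained for hyper/hypo in CpG).
#' @export
effect_report <- function(effects) {
  purrr::map_dfr(names(effects), function(nm) {
    e <- effects[[nm]]
    base <- tidyr::expand_grid(family = nm, context = "CpG",
                               direction = c("hyper", "hypo"))
    if (nrow(e) == 0) return(mutate(base, n = 0L))
    cnt <- e |>
      count(.data$context, .data$direction) |>
      mutate(family = nm) |>
      select("family", "context", "direction", "n")
    full_join(base, cnt, by = c("family", "context", "direction")) |>
      mutate(n = dplyr::coalesce(.data$n, 0L)) |>
      arrange(.data$context, .data$direction) |>
      select("family", "context", "direction", "n")
  })
}

#' Run the nine pairwise comparisons end to end
#'
#' Unites positions and calls DMCs for each comparison of the design, then
#' assembles the effect families.
#'
#' @param calls A `methylation_calls` tibble covering the 18 samples.
#' @param design A [sample_design()].
#' @param context Context to test (default `"CpG"`).
#' @param diff_threshold,q_threshold Filter thresholds
#'   (see [get_methyl_diff()]).
#' @return A list with `comparisons` (the spec table), `dmc_sets` (nine
#'   `dmc_set`s) and `effects` (an `effect_sets`).
#' @export
run_comparisons <- function(calls, design, context = "CpG",
                            diff_threshold = 25, q_threshold = 0.05) {
  comps <- enumerate_comparisons(design)
  dmc_sets <- purrr::pmap(comps, function(comparison, family, group_a,
                                          group_b) {
    sub <- filter(calls, .data$sample_id %in% c(group_a, group_b))
    united <- unite_positions(sub, context_filter = context)
    get_methyl_diff(united, group_a, group_b,
                    diff_threshold = diff_threshold,
                    q_threshold = q_threshold, comparison = comparison)
  })
  names(dmc_sets) <- comps$comparison
  list(comparisons = comps, dmc_sets = dmc_sets,
       effects = effect_sets(dmc_sets, comps))
}

#' Write an effect report as TSV
#' @param effects An `effect_sets`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_report <- function(effects, path) {
  readr::write_tsv(effect_report(effects), path, progress = FALSE)
  invisible(path)
}
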