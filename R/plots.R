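#' Plot a metagene methylation profile
#'
#' Mean methylation fraction against the scaled gene axis (upstream flank,
#' TSS to TES, downstream flank), the classic mosaic-methylome profile.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  layout <- attr(object, "layout")
  nf <- layout$n_flank_bins
  nb <- layout$body_bins
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$mean_fraction)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = c(nf + 0.5, nf + nb + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, nf + 0.5, nf + nb + 0.5, 2 * nf + nb),
      labels = c(sprintf("-%d bp", layout$flank), "TSS", "TES",
                 sprintf("+%d bp", layout$flank))) +
    ggplot2::labs(x = NULL, y = "mean methylation fraction") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of one comparison's tested sites
#'
#' Methylation difference against -log10 q, with the DMC filter thresholds
#' drawn and passing sites coloured by direction.
#'
#' @param object A `dmc_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmc_set <- function(object, ...) {
  d <- object$results |>
    mutate(status = dplyr::case_when(
      abs(.data$meth_diff) > object$diff_threshold &
        .data$q < object$q_threshold & .data$meth_diff > 0 ~ "hyper",
      abs(.data$meth_diff) > object$diff_threshold &
        .data$q < object$q_threshold ~ "hypo",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$meth_diff,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$diff_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$q_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b",
                                            hypo = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(title = object$comparison,
                  x = "methylation difference (percentage points)",
                  y = expression(-log[10] * " q")) +
    ggplot2::theme_minimal()
}

#' Bar chart of enriched GO terms
#'
#' @param object A `go_enrichment` tibble.
#' @param max_terms Show at most this many terms (smallest p first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.go_enrichment <- function(object, max_terms = 20, ...) {
  d <- head(arrange(object, .data$p), max_terms)
  lab <- if ("term_name" %in% names(d)) {
    paste0(d$go_id, " ", d$term_name)
  } else {
    d$go_id
  }
  d$label <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p), y = .data$label)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$namespace),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = expression(-log[10] * " p"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Darkness distributions of a phenotype result
#'
#' Boxplots of per-image darkness by group, the visual companion of the
#' pairwise Wilcoxon tests.
#'
#' @param object A `phenotype_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phenotype_result <- function(object, ...) {
  ggplot2::ggplot(object$measurements,
                  ggplot2::aes(x = .data$group, y = .data$darkness)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "darkness (1 - mean brightness)") +
    ggplot2::theme_minimal()
}

#' Histogram of gene-body methylation rates
#'
#' The bimodal GBMR distribution that motivates the low/high gene
#' classification.
#'
#' @param gene_meth A `gene_methylation` tibble (classified or not).
#' @param bins Histogram bin count.
#' @return A ggplot.
#' @export
plot_gbmr_distribution <- function(gene_meth, bins = 40) {
  d <- filter(gene_meth, !is.na(.data$gbmr))
  aes <- if ("meth_class" %in% names(d)) {
    ggplot2::aes(x = .data$gbmr, fill = .data$meth_class)
  } else {
    ggplot2::aes(x = .data$gbmr)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_histogram(bins = bins, colour = "white") +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "gene body methylation rate", y = "genes") +
    ggplot2::theme_minimal()
}
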