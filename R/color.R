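#' HSV summary statistics of an image
#'
#' Converts each pixel from RGB to HSV and reports the arithmetic mean
#' saturation, the darkness (1 minus the mean value/brightness channel --
#' this package's operational definition of darkness), and the circular mean
#' hue (unit-vector averaging, degrees in \[0, 360)).
#'
#' @param image An RGB array (`height x width x 3`, values in \[0,1\]) or a
#'   PNG path.
#' @param mask Optional logical matrix (`height x width`) selecting the
#'   shell pixels to measure.
#' @return A one-row tibble (class `color_measurement`): `mean_hue`,
#'   `mean_saturation`, `darkness`, `n_pixels`.
#' @export
#' @examples
#' img <- array(0, dim = c(2, 2, 3))  # pure black
#' hsb_stats(img)$darkness            # 1
hsb_stats <- function(image, mask = NULL) {
  if (is.character(image)) image <- read_shell_image(image)
  assert_that(length(dim(image)) == 3 && dim(image)[3] >= 3,
              "image must be an RGB array")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  if (!is.null(mask)) {
    assert_that(any(mask), "mask selects no pixels")
    r <- r[mask]; g <- g[mask]; b <- b[mask]
  }
  hsvm <- rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                  maxColorValue = 1)
  h_deg <- hsvm[1, ] * 360
  # circular mean; hue is undefined for grey pixels but rgb2hsv returns 0
  ang <- h_deg * pi / 180
  mh <- (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi) %% 360
  tibble(
    mean_hue = mh,
    mean_saturation = mean(hsvm[2, ]),
    darkness = 1 - mean(hsvm[3, ]),
    n_pixels = length(h_deg)
  )
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] (Royston's approximation),
#' used descriptively before the rank-based group tests.
#'
#' @param values Numeric vector, 3 to 5000 non-constant values.
#' @return A one-row tibble: `test`, `statistic` (W), `p`.
#' @export
shapiro_test <- function(values) {
  assert_that(length(values) >= 3 && length(values) <= 5000,
              "shapiro_test needs 3 to 5000 values")
  assert_that(length(unique(values)) > 1, "values are all identical")
  st <- shapiro.test(values)
  tibble(test = "shapiro", statistic = unname(st$statistic), p = st$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by enumeration of the rank-sum distribution when the combined
#' sample size is at most 25 and there are no ties; otherwise the normal
#' approximation with tie correction (and continuity correction), as in
#' [stats::wilcox.test()].
#'
#' @param a,b Numeric samples.
#' @param mode `"exact_if_small"` (default), `"exact"` or `"approx"`.
#' @return A one-row tibble: `test`, `statistic` (W), `p`.
#' @export
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p  # 0.1
wilcoxon_rank_sum <- function(a, b, mode = c("exact_if_small", "exact",
                                             "approx")) {
  mode <- match.arg(mode)
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    # a single tied value carries no rank information
    return(tibble(test = "wilcoxon",
                  statistic = length(a) * length(b) / 2, p = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
                  exact_if_small = (length(a) + length(b) <= 25) && !ties,
                  exact = TRUE,
                  approx = FALSE)
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
}

#' Color phenotyping pipeline for grouped shell images
#'
#' Measures every image with [hsb_stats()], runs a Shapiro-Wilk test per
#' group, and tests all group pairs with two-sided Wilcoxon rank-sum tests
#' on darkness and on saturation (hue is reported descriptively in the
#' measurements). This mirrors the study's protocol of ten screenshots per
#' sample followed by pairwise Wilcoxon tests.
#'
#' @param image_groups A named list: each element a list of RGB arrays (or
#'   an `image_set` tibble) for one group; at least 2 groups of at least 3
#'   images each.
#' @return A `phenotype_result` list: `measurements` (per image, with
#'   `group`), `normality` (Shapiro per group and channel), `tests`
#'   (pairwise Wilcoxon, per channel). `tidy()` returns the test table,
#'   `glance()` a one-row summary.
#' @export
phenotype_pipeline <- function(image_groups) {
  assert_that(length(image_groups) >= 2, "need at least 2 groups")
  assert_that(!is.null(names(image_groups)) && all(nzchar(names(image_groups))),
              "image_groups must be named")
  imgs <- purrr::map(image_groups, function(g) {
    if (is.data.frame(g)) g$image else g
  })
  sizes <- lengths(imgs)
  if (any(sizes < 3)) {
    abort(paste0("groups with fewer than 3 images: ",
                 paste(names(imgs)[sizes < 3], collapse = ", ")))
  }
  measurements <- purrr::imap(imgs, function(g, nm) {
    purrr::map_dfr(seq_along(g), function(i) {
      mutate(hsb_stats(g[[i]]), group = nm,
             image_id = sprintf("%s_img%02d", nm, i))
    })
  }) |>
    bind_rows() |>
    select("group", "image_id", "mean_hue", "mean_saturation", "darkness",
           "n_pixels")

  channels <- c("darkness", "mean_saturation")
  normality <- purrr::map_dfr(names(imgs), function(nm) {
    purrr::map_dfr(channels, function(ch) {
      v <- measurements[[ch]][measurements$group == nm]
      res <- if (length(unique(v)) == 1) {
        tibble(test = "shapiro", statistic = NA_real_, p = NA_real_)
      } else {
        shapiro_test(v)
      }
      mutate(res, group = nm, channel = ch)
    })
  }) |> select("group", "channel", "test", "statistic", "p")

  combos <- utils::combn(names(imgs), 2, simplify = FALSE)
  tests <- purrr::map_dfr(combos, function(pair) {
    purrr::map_dfr(channels, function(ch) {
      va <- measurements[[ch]][measurements$group == pair[1]]
      vb <- measurements[[ch]][measurements$group == pair[2]]
      mutate(wilcoxon_rank_sum(va, vb),
             comparison = paste(pair, collapse = " vs "), channel = ch)
    })
  }) |> select("comparison", "channel", "test", "statistic", "p")

  structure(list(measurements = measurements, normality = normality,
                 tests = tests),
            class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat(sprintf("<phenotype_result> %d group(s), %d image(s)\n",
              dplyr::n_distinct(x$measurements$group),
              nrow(x$measurements)))
  print(x$tests)
  invisible(x)
}

#' Write phenotype measurement and test tables as TSV
#' @param result A `phenotype_result`.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_phenotype_tables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    measurements = file.path(dir, "color_measurements.tsv"),
    normality = file.path(dir, "color_normality.tsv"),
    tests = file.path(dir, "color_tests.tsv")
  )
  readr::write_tsv(result$measurements, paths["measurements"], progress = FALSE)
  readr::write_tsv(result$normality, paths["normality"], progress = FALSE)
  readr::write_tsv(result$tests, paths["tests"], progress = FALSE)
  invisible(paths)
}
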