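hsv_to_rgb <- function(h, s, v) {
  # h in degrees, s/v in [0,1]; returns matrix with columns r, g, b in [0,1].
  # Exact double-precision conversion (no 8-bit quantization), so that
  # rgb2hsv() recovers the value channel bit for bit.
  h <- (h %% 360) / 60
  chroma <- v * s
  x <- chroma * (1 - abs(h %% 2 - 1))
  m <- v - chroma
  hi <- floor(h) %% 6
  r <- ifelse(hi == 0 | hi == 5, chroma, ifelse(hi == 1 | hi == 4, x, 0))
  g <- ifelse(hi == 1 | hi == 2, chroma, ifelse(hi == 0 | hi == 3, x, 0))
  b <- ifelse(hi == 3 | hi == 4, chroma, ifelse(hi == 2 | hi == 5, x, 0))
  cbind(r + m, g + m, b + m)
}

#' Generate synthetic shell images
#'
#' Emulates the standardized screenshots of the inner shell used for color
#' phenotyping: near-uniform images at a base HSV color whose brightness
#' (value channel) is lowered by `darkness_shift` and perturbed per pixel by
#' Gaussian noise, then clipped to \[0,1\]. Increasing `darkness_shift` by d
#' increases the measured darkness (1 - mean brightness) by d, up to noise
#' and clipping.
#'
#' @param n_images Number of images (the study captured ten per sample).
#' @param base_hsv Length-3 vector `c(h, s, v)`: hue in degrees, saturation
#'   and value in \[0,1\].
#' @param darkness_shift Amount subtracted from the value channel.
#' @param noise_sd Per-pixel Gaussian noise SD on the value channel.
#' @param width,height Image size in pixels.
#' @param seed Seed.
#' @return A tibble (class `image_set`) with `image_id` and a list-column
#'   `image` of `height x width x 3` RGB arrays in \[0,1\].
#' @export
generate_shell_images <- function(n_images, base_hsv = c(30, 0.5, 0.7),
                                  darkness_shift = 0, noise_sd = 0.02,
                                  width = 32, height = 32, seed = NULL) {
  assert_that(n_images >= 1, "n_images must be >= 1")
  assert_that(base_hsv[1] >= 0 && base_hsv[1] < 360 &&
                all(base_hsv[2:3] >= 0 & base_hsv[2:3] <= 1),
              "base_hsv must be (hue in [0,360), s and v in [0,1])")
  with_seed(seed, {
    imgs <- purrr::map(seq_len(n_images), function(i) {
      npx <- width * height
      v <- clamp01(base_hsv[3] - darkness_shift + rnorm(npx, 0, noise_sd))
      rgb <- hsv_to_rgb(rep(base_hsv[1], npx), rep(base_hsv[2], npx), v)
      array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = c(height, width, 3))
    })
    structure(tibble(image_id = sprintf("img%02d", seq_len(n_images)),
                     image = imgs),
              class = c("image_set", class(tibble())))
  })
}

#' Write / read images as 8-bit RGB PNG
#' @param images An `image_set` tibble.
#' @param dir Output directory (one PNG per image).
#' @return File paths, invisibly (writer); an RGB array (reader).
#' @export
write_shell_images <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(images$image_id, ".png"))
  purrr::walk2(images$image, paths, function(img, p) png::writePNG(img, p))
  invisible(paths)
}

#' @rdname write_shell_images
#' @param path A PNG path.
#' @export
read_shell_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Read an image stored as a plain pixel-matrix TSV
#'
#' Expects columns `r`, `g`, `b` in \[0,1\] plus `row`, `col` pixel indices.
#' @param path TSV path.
#' @return An RGB array.
#' @export
read_pixel_matrix <- function(path) {
  d <- readr::read_tsv(path, col_types = "iiddd", progress = FALSE)
  h <- max(d$row); w <- max(d$col)
  img <- array(0, dim = c(h, w, 3))
  img[cbind(d$row, d$col, 1)] <- d$r
  img[cbind(d$row, d$col, 2)] <- d$g
  img[cbind(d$row, d$col, 3)] <- d$b
  img
}
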