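#' Classify myelin pixels in a stained section
#'
#' Separates blue (myelin, luxol fast blue) pixels from the pink/purple
#' remainder of a combined hematoxylin-eosin / luxol-fast-blue stained
#' section by HSV thresholding: a pixel is myelin iff its hue falls in
#' `hue_band` (degrees) and its saturation and value clear the floors.
#'
#' @param img RGB raster: numeric array `height x width x 3`, values in
#'   \[0, 1\] (or 8-/16-bit integer scales, detected from the range).
#' @param hue_band Hue interval in degrees accepted as myelin blue
#'   (default 180-260).
#' @param sat_min Minimum saturation (default 0.15) — rejects near-gray.
#' @param val_min Minimum value (default 0.10) — rejects near-black.
#' @return Logical matrix (`height x width`): `TRUE` where myelin.
#' @export
classify_pixels <- function(img, hue_band = c(180, 260),
                            sat_min = 0.15, val_min = 0.10) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3L] < 3L) {
    stop("'img' must be an RGB array (height x width x 3)", call. = FALSE)
  }
  if (d[1L] == 0L || d[2L] == 0L) stop("image is empty", call. = FALSE)
  mx <- max(img)
  scale <- if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  r <- as.vector(img[, , 1L]) / scale
  g <- as.vector(img[, , 2L]) / scale
  b <- as.vector(img[, , 3L]) / scale
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
  hue <- hsv[1L, ] * 360
  myelin <- hue >= hue_band[1L] & hue <= hue_band[2L] &
    hsv[2L, ] >= sat_min & hsv[3L, ] >= val_min
  matrix(myelin, d[1L], d[2L])
}

#' Myelin fraction of a classified section
#'
#' The ratio of myelin (blue) pixels over all pixels of the section.
#'
#' @param mask Logical mask from [classify_pixels()].
#' @return A list of class `myelin_result`: `fraction`, `n_myelin`,
#'   `n_total`.
#' @export
myelin_fraction <- function(mask) {
  if (length(mask) == 0L) stop("mask is empty", call. = FALSE)
  n <- length(mask)
  k <- sum(mask)
  structure(list(fraction = k / n, n_myelin = k, n_total = n),
            class = "myelin_result")
}

#' @export
print.myelin_result <- function(x, ...) {
  cat(sprintf("Myelin fraction: %.3f (%d of %d pixels)\n",
              x$fraction, x$n_myelin, x$n_total))
  invisible(x)
}

#' Relation between regional stiffness and myelin content
#'
#' Ordinary least-squares line and Pearson correlation of shear modulus
#' against myelin fraction across sampled regions, the descriptive summary
#' used to relate white-matter stiffness to myelination.
#'
#' @param fraction Myelin fractions in \[0, 1\], length >= 3, non-constant.
#' @param modulus_kpa Elastic shear moduli in kPa, same length.
#' @return A list of class `myelin_relation`: `slope` (kPa per unit
#'   fraction), `intercept` (kPa), `correlation`, `n`, and the underlying
#'   `lm` fit.
#' @export
stiffness_myelin_relation <- function(fraction, modulus_kpa) {
  if (length(fraction) != length(modulus_kpa)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(fraction) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(fraction) == 0) {
    stop("myelin fractions are constant; regression is degenerate", call. = FALSE)
  }
  fit <- stats::lm(modulus_kpa ~ fraction)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 correlation = stats::cor(fraction, modulus_kpa),
                 n = length(fraction),
                 fit = fit),
            class = "myelin_relation")
}

#' @export
print.myelin_relation <- function(x, ...) {
  cat(sprintf("Stiffness-myelin relation (n = %d):\n", x$n))
  cat(sprintf("  modulus = %.4g + %.4g * fraction [kPa],  r = %.3f\n",
              x$intercept, x$slope, x$correlation))
  invisible(x)
}

#' Read a histology image from PNG
#'
#' @param path PNG file path.
#' @return Numeric RGB array in \[0, 1\].
#' @export
read_histology <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG images requires the 'png' package", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) stop("grayscale image: need 3 channels", call. = FALSE)
  img[, , 1:3, drop = FALSE]
}
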