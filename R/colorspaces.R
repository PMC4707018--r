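#' Gaussian color model transform
#'
#' Maps an RGB image into the Gaussian color model, a linear opponent space
#' whose components approximate the Gaussian-weighted spectral energy
#' distribution and its first two wavelength derivatives at
#' \eqn{\lambda_0 \simeq 520} nm with scale \eqn{\sigma_\lambda \simeq 55} nm.
#' Per pixel,
#' \deqn{(\hat E, \hat E_\lambda, \hat E_{\lambda\lambda})^T = M (R, G, B)^T}
#' with the fixed matrix
#' \preformatted{ M = | 0.06  0.63  0.27 |
#'     | 0.30  0.04 -0.35 |
#'     | 0.34 -0.60  0.17 |}
#'
#' @param img an H x W x 3 RGB array with values in `[0, 1]`.
#' @return an object of class `gaussian_color`: a list with matrices `e`,
#'   `e_lambda`, `e_lambda2` (each H x W) and metadata `lambda0` (520),
#'   `sigma_lambda` (55).
#' @seealso [gaussian_to_normalized()]
#' @export
rgb_to_gaussian <- function(img) {
  assert_rgb(img)
  M <- gaussian_color_matrix()
  d <- dim(img)
  px <- matrix(img, d[1] * d[2], 3L)  # columns R,G,B
  out <- px %*% t(M)
  structure(
    list(e = matrix(out[, 1], d[1], d[2]),
         e_lambda = matrix(out[, 2], d[1], d[2]),
         e_lambda2 = matrix(out[, 3], d[1], d[2]),
         lambda0 = 520, sigma_lambda = 55),
    class = "gaussian_color")
}

# the fixed RGB -> (E, E_lambda, E_lambdalambda) matrix
gaussian_color_matrix <- function() {
  matrix(c(0.06, 0.63, 0.27,
           0.30, 0.04, -0.35,
           0.34, -0.60, 0.17), 3L, 3L, byrow = TRUE)
}

#' Normalized-color reflectance invariant
#'
#' Computes \eqn{\hat C_\lambda = \hat E_\lambda / \hat E}, the normalized
#' color of the Gaussian color model. Up to sensor noise this quantity is a
#' reflectance property of the imaged surface, invariant to illumination
#' intensity: scaling RGB by a constant leaves it unchanged. The division is
#' guarded by `epsilon` where \eqn{\hat E} is near zero (near-black pixels).
#'
#' @param g a `gaussian_color` object from [rgb_to_gaussian()].
#' @param epsilon small positive guard for the denominator (default `1e-6`).
#' @return a list of class `normalized_color` with matrix `c_lambda` and the
#'   guard `epsilon_guard`.
#' @export
gaussian_to_normalized <- function(g, epsilon = 1e-6) {
  stopifnot(inherits(g, "gaussian_color"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar", call. = FALSE)
  cl <- g$e_lambda / pmax(g$e, epsilon)
  structure(list(c_lambda = cl, epsilon_guard = epsilon),
            class = "normalized_color")
}

#' Chromaticity-weighted intensity
#'
#' Intensity estimate in which each channel is weighted by its own
#' chromaticity fraction:
#' \deqn{I = \frac{R}{R+G+B}R + \frac{G}{R+G+B}G + \frac{B}{R+G+B}B
#'        = \frac{R^2+G^2+B^2}{R+G+B}.}
#' Black pixels (R+G+B = 0) map to 0 by convention.
#'
#' @param img an H x W x 3 RGB array in `[0, 1]`.
#' @return an H x W matrix of intensities.
#' @export
intensity_chromatic <- function(img) {
  assert_rgb(img)
  s <- img[, , 1] + img[, , 2] + img[, , 3]
  q <- img[, , 1]^2 + img[, , 2]^2 + img[, , 3]^2
  out <- ifelse(s > 0, q / pmax(s, .Machine$double.xmin), 0)
  matrix(out, dim(img)[1], dim(img)[2])
}

#' RGB to full-range BT.601 YCbCr
#'
#' ITU-R BT.601 full-range transform on unit-interval channels:
#' `Y = 0.299 R + 0.587 G + 0.114 B`, with `Cb`, `Cr` the scaled blue/red
#' color differences centered at 0.5.
#'
#' @param img an H x W x 3 RGB array in `[0, 1]`.
#' @return a list with H x W matrices `y`, `cb`, `cr`.
#' @export
rgb_to_ycbcr <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2])
  g <- matrix(img[, , 2], d[1], d[2])
  b <- matrix(img[, , 3], d[1], d[2])
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 0.5 + (b - y) * (0.5 / (1 - 0.114))
  cr <- 0.5 + (r - y) * (0.5 / (1 - 0.299))
  list(y = y, cb = cb, cr = cr)
}

#' Inverse of [rgb_to_ycbcr()]
#'
#' @param y,cb,cr H x W matrices as produced by [rgb_to_ycbcr()].
#' @param clip clip the result into `[0, 1]` (default `TRUE`).
#' @return an H x W x 3 RGB array.
#' @export
ycbcr_to_rgb <- function(y, cb, cr, clip = TRUE) {
  r <- y + (cr - 0.5) / (0.5 / (1 - 0.299))
  b <- y + (cb - 0.5) / (0.5 / (1 - 0.114))
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(c(r, g, b), c(nrow(y), ncol(y), 3L))
  if (clip) out <- clip01(out)
  out
}

#' Luminance of an RGB image
#'
#' BT.601 luma, the `Y` plane of [rgb_to_ycbcr()].
#'
#' @inheritParams rgb_to_ycbcr
#' @return an H x W matrix in `[0, 1]`.
#' @export
luminance <- function(img) rgb_to_ycbcr(img)$y
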