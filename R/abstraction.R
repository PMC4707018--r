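#' Bilateral filter
#'
#' Edge-preserving smoothing that replaces each pixel by a normalized
#' weighted average of nearby (spatial Gaussian `s`, sd `sigma_s`) and
#' similar (range Gaussian `r`, sd `sigma_r`) pixels:
#' \deqn{J(x) = \frac{1}{k(x)} \sum_{n \in \Omega} s(n-x)\, r(f(n)-f(x))\, f(n),
#'   \qquad k(x) = \sum_{n \in \Omega} s(n-x)\, r(f(n)-f(x)),}
#' with \eqn{\Omega} the `(2 window_radius + 1)` square window and reflected
#' borders. Because weights are normalized, constants are fixed points and
#' the output range never exceeds the input range.
#'
#' @param img an H x W matrix.
#' @param sigma_s spatial standard deviation, pixels (default 3).
#' @param sigma_r range standard deviation, intensity units (default 0.2:
#'   comfortably above tissue-texture amplitude, well below the stain/tissue
#'   luminance gap).
#' @param window_radius truncation radius of the spatial kernel, pixels
#'   (default 7; at least `2 * sigma_s` is recommended).
#' @return the filtered H x W matrix.
#' @export
bilateral <- function(img, sigma_s = 3, sigma_r = 0.2, window_radius = 7) {
  assert_plane(img)
  if (sigma_s <= 0 || sigma_r <= 0)
    stop("sigma_s and sigma_r must be positive", call. = FALSE)
  r <- as.integer(window_radius)
  if (r < 1) stop("degenerate window: window_radius must be >= 1", call. = FALSE)
  bilateral_cpp(img, sigma_s, sigma_r, r)
}

#' Large-scale layer
#'
#' A single bilateral pass over the first Gaussian color component
#' \eqn{\hat E}: the smooth, edge-preserving backbone of the image used as
#' the large-scale layer of the decomposition.
#'
#' @param g a `gaussian_color` object ([rgb_to_gaussian()]).
#' @param sigma_s,sigma_r,window_radius bilateral parameters, see
#'   [bilateral()].
#' @return an H x W matrix.
#' @export
extract_large_scale <- function(g, sigma_s = 3, sigma_r = 0.2,
                                window_radius = 7) {
  stopifnot(inherits(g, "gaussian_color"))
  bilateral(g$e, sigma_s, sigma_r, window_radius)
}

#' Detail layer from normalized color
#'
#' The detail layer is a multiplicative-gain residual of the normalized
#' color \eqn{\hat C_\lambda} after `n_iters` bilateral passes:
#' \deqn{D = 1 + \mathrm{gain} \cdot (\hat C_\lambda - B^{n}(\hat C_\lambda)),}
#' clipped into `[0, 2]`. Featureless regions map to the neutral value 1, so
#' the layer acts as a sharpness-restoring gain when multiplied back into the
#' recombined image; the residual captures stain detail that survives the
#' reflectance-invariant normalization.
#'
#' @param nc a `normalized_color` object ([gaussian_to_normalized()]).
#' @param sigma_s,sigma_r,window_radius bilateral parameters.
#' @param n_iters number of bilateral passes before the residual (default 2).
#' @param gain residual amplification (default 1; the residual also carries
#'   per-pixel chromatic noise, which larger gains re-inject into the
#'   background).
#' @return an H x W matrix in `[0, 2]`, neutral at 1.
#' @export
extract_detail <- function(nc, sigma_s = 3, sigma_r = 0.2, window_radius = 7,
                           n_iters = 2, gain = 1) {
  stopifnot(inherits(nc, "normalized_color"))
  if (n_iters < 1) stop("n_iters must be >= 1", call. = FALSE)
  base <- nc$c_lambda
  for (i in seq_len(n_iters))
    base <- bilateral(base, sigma_s, sigma_r, window_radius)
  out <- 1 + gain * (nc$c_lambda - base)
  out[] <- pmin(2, pmax(0, out))
  out
}

#' Recombine color, large-scale and detail layers
#'
#' Element-by-element product of the (bias-corrected) color layer, the
#' normalized large-scale layer and the detail layer, clipped into `[0, 1]`:
#' \deqn{\mathrm{out}_c = \mathrm{clip}_{[0,1]}(\mathrm{color}_c \times
#'   \mathrm{LS}_{norm} \times D).}
#' The large-scale layer is normalized by its maximum (so it is a gain
#' \eqn{\le 1} that preserves relative intensities); a constant layer acts
#' as the neutral factor 1. Normalizing by the maximum rather than
#' stretching to the full `[0, 1]` range matters: a min-max stretch
#' amplifies residual background structure by `1 / (max - min)` and crushes
#' all dark structure toward zero, which works against the goal of a
#' homogeneous background with salient stained regions.
#'
#' @param color_layer an H x W x 3 RGB array.
#' @param large_scale an H x W matrix (any range; normalized internally).
#' @param detail an H x W matrix, neutral at 1.
#' @return an H x W x 3 RGB array in `[0, 1]`.
#' @export
recombine <- function(color_layer, large_scale, detail) {
  assert_rgb(color_layer, "color_layer")
  d <- dim(color_layer)
  if (!identical(dim(large_scale), d[1:2]) || !identical(dim(detail), d[1:2]))
    stop("layer shapes disagree", call. = FALSE)
  mx <- max(large_scale)
  ls_norm <- if (mx > 0) large_scale / mx else large_scale + 1
  f <- ls_norm * detail
  out <- color_layer
  for (c in 1:3) out[, , c] <- clip01(color_layer[, , c] * f)
  out
}

#' Soft luminance quantization
#'
#' Abstracts the salient regions by pseudo-quantizing the luminance
#' \eqn{h(\hat s)} of the recombined image into `n_bins` bins of width
#' \eqn{\Delta q = 1/n_{bins}}:
#' \deqn{Q = q_{nearest} + \frac{\Delta q}{2}
#'   \tanh(\kappa_q (h(\hat s) - q_{nearest})),}
#' where \eqn{q_{nearest}} is the closest bin boundary and \eqn{\kappa_q}
#' controls the sharpness of the transition between bins. As
#' \eqn{\kappa_q \to \infty} this approaches hard nearest-bin quantization;
#' the output never departs more than \eqn{\Delta q / 2} from
#' \eqn{q_{nearest}}. Chrominance is passed through untouched.
#'
#' @param img an H x W x 3 RGB array in `[0, 1]`.
#' @param n_bins number of luminance bins (default 8).
#' @param kappa_q transition sharpness; default `8 * n_bins` (i.e.
#'   `8 / Delta_q`), following the cartoon-abstraction convention of scaling
#'   sharpness to the bin width.
#' @return an H x W x 3 RGB array with quantized luminance.
#' @export
quantize_luminance <- function(img, n_bins = 8, kappa_q = NULL) {
  assert_rgb(img)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  dq <- 1 / n_bins
  if (is.null(kappa_q)) kappa_q <- 8 / dq
  if (kappa_q <= 0) stop("kappa_q must be positive", call. = FALSE)
  yc <- rgb_to_ycbcr(img)
  q_near <- round(yc$y / dq) * dq
  q <- q_near + (dq / 2) * tanh(kappa_q * (yc$y - q_near))
  ycbcr_to_rgb(clip01(q), yc$cb, yc$cr)
}

#' Salient-region filtering pipeline
#'
#' The full image-abstraction flow: chromaticity-weighted intensity and a
#' Niblack threshold surface estimate the light bias, which is divided out
#' of every channel; the corrected image is decomposed into a large-scale
#' layer (one bilateral pass over \eqn{\hat E}) and a detail layer (bilateral
#' residual of \eqn{\hat C_\lambda}); layers are recombined multiplicatively
#' with the color layer; and the result is abstracted by soft luminance
#' quantization. Deterministic for a fixed configuration.
#'
#' @param img an H x W x 3 RGB array in `[0, 1]`.
#' @param config a configuration list, see [vesselab_config()]. Keys under
#'   `niblack`, `bilateral`, `detail`, `quant` and `filter` are honoured.
#' @return an H x W x 3 RGB array: the abstracted image. The intermediate
#'   layers are attached as attribute `"layers"` (a list with
#'   `color_layer`, `large_scale`, `detail`).
#' @export
filter_pipeline <- function(img, config = vesselab_config()) {
  assert_rgb(img)
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("filter_pipeline [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  color_layer <- stage("light_bias", {
    I <- intensity_chromatic(img)
    surf <- niblack_surface(I, cfg$niblack$window_radius, cfg$niblack$k)
    ratio <- img
    tmax <- pmax(surf$t, cfg$normalized$epsilon)
    for (c in 1:3) ratio[, , c] <- img[, , c] / tmax
    ratio / max(ratio, 1e-12)
  })
  g <- stage("gaussian", rgb_to_gaussian(color_layer))
  nc <- stage("normalized", gaussian_to_normalized(g, cfg$normalized$epsilon))
  ls <- stage("large_scale", {
    if (isTRUE(cfg$filter$neutral_large_scale)) {
      matrix(1, nrow(g$e), ncol(g$e))
    } else {
      extract_large_scale(g, cfg$bilateral$sigma_s, cfg$bilateral$sigma_r,
                          cfg$bilateral$window_radius)
    }
  })
  dt <- stage("detail", {
    if (isTRUE(cfg$filter$neutral_detail)) {
      matrix(1, nrow(g$e), ncol(g$e))
    } else {
      extract_detail(nc, cfg$bilateral$sigma_s, cfg$bilateral$sigma_r,
                     cfg$bilateral$window_radius, cfg$detail$n_iters,
                     cfg$detail$gain)
    }
  })
  rec <- stage("recombine", recombine(color_layer, ls, dt))
  out <- stage("quantize",
               quantize_luminance(rec, cfg$quant$n_bins, cfg$quant$kappa_q))
  attr(out, "layers") <- list(color_layer = color_layer, large_scale = ls,
                              detail = dt)
  out
}
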