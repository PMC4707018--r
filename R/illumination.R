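#' Niblack threshold surface
#'
#' Local adaptive threshold surface \eqn{T = m + k s}, where `m` and `s` are
#' the mean and (population) standard deviation of the intensity over a
#' `(2r+1) x (2r+1)` neighborhood of each pixel and `k` is a negative
#' constant. Smoothly tracking the local gray level, the surface approximates
#' the distribution of the platform illumination; dividing the image by it
#' removes smooth light bias. Borders are handled by reflection.
#'
#' Computed with integral images (summed-area tables), so cost is independent
#' of the window radius.
#'
#' @param img an H x W intensity matrix.
#' @param window_radius neighborhood radius `r` in pixels (default 15).
#' @param k multiplier on the local standard deviation (default -0.2).
#' @return a list of class `threshold_surface` with matrix `t`, and the
#'   parameters `window_radius`, `k`.
#' @export
niblack_surface <- function(img, window_radius = 15, k = -0.2) {
  assert_plane(img)
  r <- as.integer(window_radius)
  if (r < 1) stop("window_radius must be >= 1", call. = FALSE)
  if (2L * r + 1L > min(dim(img)))
    stop("window (", 2 * r + 1, " px) larger than image", call. = FALSE)
  m <- box_mean(img, r)
  m2 <- box_mean(img * img, r)
  s <- sqrt(pmax(m2 - m * m, 0))
  structure(list(t = m + k * s, window_radius = r, k = k),
            class = "threshold_surface")
}

# sliding-window mean over (2r+1)^2 windows with reflected borders,
# via an integral image on the reflect-padded matrix
box_mean <- function(x, r) {
  p <- pad_reflect(x, r)
  S <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  S <- rbind(0, cbind(0, t(S)))
  H <- nrow(x); W <- ncol(x); w <- 2L * r + 1L
  # window for pixel (i,j) covers padded rows i..i+2r, cols j..j+2r
  i1 <- seq_len(H); j1 <- seq_len(W)
  (S[i1 + w, j1 + w, drop = FALSE] - S[i1, j1 + w, drop = FALSE] -
     S[i1 + w, j1, drop = FALSE] + S[i1, j1, drop = FALSE]) / (w * w)
}

pad_reflect <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  ri <- reflect_indices(H, r)
  ci <- reflect_indices(W, r)
  x[ri, ci, drop = FALSE]
}

reflect_indices <- function(n, r) {
  idx <- seq.int(1L - r, n + r)
  vapply(idx, function(i) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }, integer(1))
}

#' Divide out a light-bias surface
#'
#' Reduces smooth illumination bias by dividing the intensity image by a
#' threshold surface (see [niblack_surface()]), then rescaling the ratio
#' image into `[0, 1]` by its maximum.
#'
#' @param img an H x W intensity matrix.
#' @param surface a `threshold_surface`, or a bare matrix of the same shape.
#' @param epsilon guard for near-zero surface values (default `1e-6`).
#' @return an H x W matrix in `[0, 1]`.
#' @export
remove_light_bias <- function(img, surface, epsilon = 1e-6) {
  assert_plane(img)
  t_surf <- if (inherits(surface, "threshold_surface")) surface$t else surface
  if (!identical(dim(t_surf), dim(img)))
    stop("surface shape does not match image", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar", call. = FALSE)
  out <- img / pmax(t_surf, epsilon)
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

#' Sigmoid contrast enhancement
#'
#' Spatial-domain contrast stretch
#' \eqn{g(x) = 1 / (1 + e^{-\mathrm{gain}(x - \mathrm{midpoint})})},
#' min-max rescaled to `[0, 1]`. The map is strictly monotone, so pixel rank
#' order is preserved exactly; contrast is expanded around the midpoint
#' (by default the image median) and compressed in the tails.
#'
#' @param img an H x W intensity matrix in `[0, 1]`.
#' @param gain slope at the midpoint (default 10).
#' @param midpoint center of the transition: a number in `[0, 1]`,
#'   `"otsu"` (default, the Otsu cut of the image — placing the transition
#'   at the class boundary stretches between-class contrast while
#'   compressing within-class texture) or `"median"`.
#' @return an H x W matrix in `[0, 1]`.
#' @export
sigmoid_enhance <- function(img, gain = 10, midpoint = "otsu") {
  assert_plane(img)
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  mid <- if (identical(midpoint, "median")) median(img)
         else if (identical(midpoint, "otsu"))
           tryCatch(otsu_threshold(img), error = function(e) median(img))
         else midpoint
  if (!is.numeric(mid) || length(mid) != 1L || mid < 0 || mid > 1)
    stop("midpoint must be in [0, 1], \"otsu\" or \"median\"", call. = FALSE)
  out <- 1 / (1 + exp(-gain * (img - mid)))
  normalize01(out, const = 0.5)
}
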