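# Independent oracle implementations and fixture builders used across the
# suite. Oracles are deliberately naive (double loops, exhaustive search)
# and share no code with the package internals they check.

reflect_ix <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# naive windowed mean/sd Niblack surface, reflect borders
naive_niblack <- function(img, r, k) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, img[reflect_ix(i + di, H), reflect_ix(j + dj, W)])
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    out[i, j] <- m + k * s
  }
  out
}

# naive double-loop bilateral filter, reflect borders
naive_bilateral <- function(img, sigma_s, sigma_r, radius) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    fc <- img[i, j]
    num <- 0; den <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      fn <- img[reflect_ix(i + di, H), reflect_ix(j + dj, W)]
      w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2)) *
        exp(-(fn - fc)^2 / (2 * sigma_r^2))
      num <- num + w * fn
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# truncated Gaussian convolution with reflect borders (bilateral limit as
# sigma_r -> Inf)
naive_gauss_conv <- function(img, sigma_s, radius) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    num <- 0; den <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
      num <- num + w * img[reflect_ix(i + di, H), reflect_ix(j + dj, W)]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# exhaustive 256-candidate Otsu: minimize within-class variance directly
exhaustive_otsu <- function(img) {
  v <- as.numeric(img)
  lev <- pmin(255L, pmax(0L, as.integer(round(v * 255))))
  vals <- lev / 255
  best_k <- NA
  best <- Inf
  for (k in 0:254) {
    lo <- vals[lev <= k]; hi <- vals[lev > k]
    if (!length(lo) || !length(hi)) next
    wcv <- length(lo) * mean((lo - mean(lo))^2) +
      length(hi) * mean((hi - mean(hi))^2)
    if (wcv < best - 1e-15) { best <- wcv; best_k <- k }
  }
  (best_k + 0.5) / 255
}

# exact all-pairs GPAC region force via the full dissimilarity matrix
naive_gpac_force <- function(feature, mask) {
  v <- as.numeric(feature)
  D <- outer(v, v, function(a, b) (a - b)^2)
  inn <- as.numeric(mask)
  d_in <- as.numeric(D %*% inn) / sum(inn)
  d_out <- as.numeric(D %*% (1 - inn)) / sum(1 - inn)
  matrix(d_in - d_out, nrow(feature))
}

# two-constant rectangle fixture for GPAC tests
rect_fixture <- function(H = 64, W = 64, noise = 0, seed = 1) {
  set.seed(seed)
  truth <- matrix(FALSE, H, W)
  truth[round(H * 0.28):round(H * 0.72), round(W * 0.34):round(W * 0.78)] <- TRUE
  f <- matrix(0.2, H, W)
  f[truth] <- 0.8
  if (noise > 0) f <- f + matrix(rnorm(H * W, 0, noise), H, W)
  list(f = f, truth = truth)
}

# a brown annulus (wall) with pale lumen on pink background
annulus_fixture <- function(H = 64, W = 64, cx = 32, cy = 32, r_lumen = 10,
                            wall = 4) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (yy - cy)^2 + (xx - cx)^2
  lumen <- d2 <= r_lumen^2
  outer_m <- d2 <= (r_lumen + wall)^2
  wall_m <- outer_m & !lumen
  img <- array(0, c(H, W, 3))
  cols <- list(bg = c(0.85, 0.75, 0.78), wall = c(0.45, 0.30, 0.20),
               lumen = c(0.95, 0.93, 0.90))
  for (c in 1:3) {
    p <- matrix(cols$bg[c], H, W)
    p[wall_m] <- cols$wall[c]
    p[lumen] <- cols$lumen[c]
    img[, , c] <- p
  }
  list(img = img, lumen = lumen, wall = wall_m, disk = outer_m)
}

# extract the bright-phase mask of a converged contour state
bright_mask <- function(st, feature) {
  m <- st$phi > 0
  if (mean(feature[m]) < mean(feature[!m])) m <- !m
  m
}
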