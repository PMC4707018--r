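#' Synthetic IHC vessel image specification
#'
#' Parameters fully determining a synthetic immunostained vessel image and
#' its ground truth. Vessels are elliptical annuli: a brown stained wall
#' (emulating CD31-positive endothelium) around a pale lumen, laid on a
#' pinkish tissue background with stained clutter blobs, a smooth
#' multiplicative illumination ramp and per-channel Gaussian noise.
#'
#' @param height,width canvas size in pixels (default 192 x 192).
#' @param n_vessels number of vessels (default 5); vessels never overlap.
#' @param lumen_radius_range min/max lumen radius, pixels (default `c(5, 9)`).
#' @param wall_thickness_range min/max wall thickness, pixels
#'   (default `c(3, 5)`).
#' @param wall_color_mean RGB of the stained wall (default
#'   `c(0.45, 0.30, 0.20)`, a DAB-like brown).
#' @param lumen_color_mean RGB of the lumen (default `c(0.95, 0.93, 0.90)`).
#' @param background_color_mean RGB of the tissue background (default
#'   `c(0.85, 0.75, 0.78)`).
#' @param clutter_color_mean RGB of non-vessel stained blobs (default
#'   `c(0.55, 0.45, 0.60)`, a hematoxylin-like purple).
#' @param clutter_density target fraction of the canvas covered by clutter
#'   blobs (default 0.03).
#' @param texture_sd amplitude (sd) of the spatially correlated tissue
#'   texture added to background and clutter, in luminance units
#'   (default 0.05); the texture field is smoothed white noise with a
#'   correlation scale of a few pixels, emulating the granular appearance
#'   of counterstained tissue.
#' @param noise_sigma per-channel Gaussian sensor noise sd (default 0.02).
#' @param illumination_ramp maximum relative brightness change across the
#'   image (default 0.2).
#' @param max_eccentricity maximum ellipse axis ratio (default 1.8).
#' @param seed integer seed; the generator is deterministic given the spec.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 192, width = 192, n_vessels = 5,
                           lumen_radius_range = c(5, 9),
                           wall_thickness_range = c(3, 5),
                           wall_color_mean = c(0.45, 0.30, 0.20),
                           lumen_color_mean = c(0.95, 0.93, 0.90),
                           background_color_mean = c(0.85, 0.75, 0.78),
                           clutter_color_mean = c(0.55, 0.45, 0.60),
                           clutter_density = 0.03, texture_sd = 0.05,
                           noise_sigma = 0.02,
                           illumination_ramp = 0.2, max_eccentricity = 1.8,
                           seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_vessels = as.integer(n_vessels),
               lumen_radius_range = lumen_radius_range,
               wall_thickness_range = wall_thickness_range,
               wall_color_mean = wall_color_mean,
               lumen_color_mean = lumen_color_mean,
               background_color_mean = background_color_mean,
               clutter_color_mean = clutter_color_mean,
               clutter_density = clutter_density, texture_sd = texture_sd,
               noise_sigma = noise_sigma,
               illumination_ramp = illumination_ramp,
               max_eccentricity = max_eccentricity, seed = as.integer(seed))
  stopifnot(spec$height >= 32, spec$width >= 32, spec$n_vessels >= 0,
            all(spec$lumen_radius_range > 0),
            all(spec$wall_thickness_range > 0),
            all(unlist(spec[c("wall_color_mean", "lumen_color_mean",
                              "background_color_mean",
                              "clutter_color_mean")]) >= 0),
            all(unlist(spec[c("wall_color_mean", "lumen_color_mean",
                              "background_color_mean",
                              "clutter_color_mean")]) <= 1),
            spec$clutter_density >= 0, spec$texture_sd >= 0,
            spec$noise_sigma >= 0,
            spec$illumination_ramp >= 0, spec$max_eccentricity >= 1)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic IHC vessel image with ground truth
#'
#' Draws `n_vessels` non-overlapping elliptical annuli (rejection sampling
#' on centers with a pairwise-distance constraint), paints walls, lumens,
#' background and clutter blobs with per-pixel color texture, applies a
#' multiplicative illumination ramp in a random direction, and finally adds
#' Gaussian noise. Ground-truth masks (wall plus lumen per vessel) are
#' recorded *before* noise, so truth is independent of `noise_sigma`.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `vessel_synth`: `image` (H x W x 3 in `[0, 1]`),
#'   `truth` (list with `vessel_mask`, `n_vessels`, `per_vessel_masks`),
#'   and `spec`.
#' @export
generate_vessel_image <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  H <- spec$height; W <- spec$width
  s_max <- sqrt(spec$max_eccentricity)
  r_out_max <- (max(spec$lumen_radius_range) +
                  max(spec$wall_thickness_range)) * s_max
  # sample vessel geometry first, then place centers by rejection sampling
  n <- spec$n_vessels
  lum_r <- runif(n, spec$lumen_radius_range[1], spec$lumen_radius_range[2])
  wall_t <- runif(n, spec$wall_thickness_range[1],
                  spec$wall_thickness_range[2])
  ecc <- runif(n, 1, spec$max_eccentricity)
  theta <- runif(n, 0, pi)
  r_out <- (lum_r + wall_t) * sqrt(ecc)
  margin <- r_out + 3
  centers <- matrix(NA_real_, n, 2)
  attempts <- 0L
  i <- 1L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > 10000L)
      stop("infeasible vessel packing: ", n, " vessels of outer radius up to ",
           round(r_out_max, 1), " px do not fit a ", H, " x ", W, " canvas",
           call. = FALSE)
    cy <- runif(1, margin[i], H - margin[i])
    cx <- runif(1, margin[i], W - margin[i])
    ok <- TRUE
    if (i > 1L) {
      d <- sqrt((centers[seq_len(i - 1L), 1] - cy)^2 +
                  (centers[seq_len(i - 1L), 2] - cx)^2)
      ok <- all(d >= r_out[seq_len(i - 1L)] + r_out[i] + 4)
    }
    if (ok) { centers[i, ] <- c(cy, cx); i <- i + 1L }
  }
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  per_vessel <- vector("list", n)
  wall_all <- matrix(FALSE, H, W)
  lumen_all <- matrix(FALSE, H, W)
  for (v in seq_len(n)) {
    s <- sqrt(ecc[v])
    dy <- yy - centers[v, 1]; dx <- xx - centers[v, 2]
    u <- dx * cos(theta[v]) + dy * sin(theta[v])
    w <- -dx * sin(theta[v]) + dy * cos(theta[v])
    outer_m <- (u / ((lum_r[v] + wall_t[v]) * s))^2 +
      (w / ((lum_r[v] + wall_t[v]) / s))^2 <= 1
    lumen_m <- (u / (lum_r[v] * s))^2 + (w / (lum_r[v] / s))^2 <= 1
    per_vessel[[v]] <- outer_m
    wall_all <- wall_all | (outer_m & !lumen_m)
    lumen_all <- lumen_all | lumen_m
  }
  vessel_mask <- wall_all | lumen_all
  # clutter blobs in the background, avoiding vessels (with a 3 px margin)
  clutter <- matrix(FALSE, H, W)
  clutter_id <- matrix(0L, H, W)
  forbidden <- if (any(vessel_mask)) dilate_mask(vessel_mask, 3) else vessel_mask
  target <- spec$clutter_density * H * W
  tries <- 0L
  n_blob <- 0L
  while (sum(clutter) < target && tries < 4000L) {
    tries <- tries + 1L
    r <- runif(1, 2, 6)
    cy <- runif(1, 1, H); cx <- runif(1, 1, W)
    blob <- (yy - cy)^2 + (xx - cx)^2 <= r^2
    if (any(blob & forbidden)) next
    n_blob <- n_blob + 1L
    clutter <- clutter | blob
    clutter_id[blob] <- n_blob
  }
  # paint: background, clutter (per-blob color jitter), wall, lumen
  img <- array(0, c(H, W, 3))
  wall_tex <- matrix(rnorm(H * W, 0, 0.04), H, W)
  # correlated tissue texture: smoothed white noise, correlation scale ~2 px
  bg_tex <- box_mean(matrix(rnorm(H * W), H, W), 2L)
  if (spec$texture_sd > 0 && sd(bg_tex) > 0)
    bg_tex <- bg_tex / sd(bg_tex) * spec$texture_sd
  else bg_tex <- bg_tex * 0
  blob_jit <- if (n_blob > 0L) matrix(rnorm(3L * n_blob, 0, 0.05), n_blob, 3L)
              else matrix(0, 0, 3)
  for (c in 1:3) {
    plane <- spec$background_color_mean[c] + bg_tex
    if (n_blob > 0L) {
      jit <- c(0, blob_jit[, c])[clutter_id + 1L]
      plane[clutter] <- spec$clutter_color_mean[c] + jit[clutter] +
        bg_tex[clutter]
    }
    plane[wall_all] <- spec$wall_color_mean[c] + wall_tex[wall_all]
    plane[lumen_all] <- spec$lumen_color_mean[c]
    img[, , c] <- plane
  }
  # multiplicative illumination ramp along a random direction
  if (spec$illumination_ramp > 0) {
    phi <- runif(1, 0, 2 * pi)
    proj <- (yy / H) * sin(phi) + (xx / W) * cos(phi)
    proj <- (proj - min(proj)) / max(diff(range(proj)), 1e-12)
    ramp <- 1 + spec$illumination_ramp * (proj - 0.5)
    for (c in 1:3) img[, , c] <- img[, , c] * ramp
  }
  img <- clip01(img)
  truth <- list(vessel_mask = vessel_mask, n_vessels = n,
                per_vessel_masks = per_vessel)
  if (spec$noise_sigma > 0)
    img <- clip01(img + array(rnorm(length(img), 0, spec$noise_sigma),
                              dim(img)))
  structure(list(image = img, truth = truth, spec = spec),
            class = "vessel_synth")
}

#' Generate a difficulty-sweep suite of synthetic images
#'
#' Produces `n_images` image/truth pairs sweeping `clutter_density` and
#' `noise_sigma` over a fixed grid around the base spec, with one derived
#' pseudo-random stream per image (from `seed` and the image index), so the
#' suite is order-independent and reproducible from its manifest.
#'
#' @param base_spec a [synthetic_spec()] giving the shared parameters.
#' @param n_images number of images (default 10).
#' @param seed suite seed (default `base_spec$seed`).
#' @return a list of class `vessel_suite`: `images` (list of
#'   `vessel_synth`) and `manifest` (data.frame with `id`, `seed`,
#'   `clutter_density`, `noise_sigma`, `clean`).
#' @export
generate_suite <- function(base_spec = synthetic_spec(), n_images = 10,
                           seed = base_spec$seed) {
  stopifnot(n_images >= 1)
  if (n_images == 1L) {
    manifest <- data.frame(id = 1L, seed = base_spec$seed,
                           clutter_density = base_spec$clutter_density,
                           noise_sigma = base_spec$noise_sigma,
                           clean = base_spec$clutter_density == 0)
    return(structure(list(images = list(generate_vessel_image(base_spec)),
                          manifest = manifest), class = "vessel_suite"))
  }
  clutters <- rep(seq(0, 2, length.out = ceiling(n_images / 2)) *
                    base_spec$clutter_density, each = 2, length.out = n_images)
  noises <- rep(c(0.5, 1.5) * base_spec$noise_sigma, length.out = n_images)
  seeds <- (as.numeric(seed) * 1009 + seq_len(n_images) * 9973) %% 2147483647
  manifest <- data.frame(id = seq_len(n_images), seed = as.integer(seeds),
                         clutter_density = clutters, noise_sigma = noises,
                         clean = clutters == 0)
  images <- lapply(seq_len(n_images), function(i) {
    sp <- base_spec
    sp$clutter_density <- manifest$clutter_density[i]
    sp$noise_sigma <- manifest$noise_sigma[i]
    sp$seed <- manifest$seed[i]
    generate_vessel_image(sp)
  })
  structure(list(images = images, manifest = manifest),
            class = "vessel_suite")
}
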