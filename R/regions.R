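#' Otsu threshold
#'
#' Global bimodal threshold minimizing the within-class intensity variance
#' of the two classes it induces, evaluated over 256 gray levels on `[0, 1]`.
#' Ties are broken toward the lower threshold.
#'
#' @param img a numeric matrix or vector with at least two distinct values.
#' @return the threshold as a real number in `[0, 1]`; pixels strictly above
#'   it form the bright class.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  if (!all(is.finite(v))) stop("non-finite values", call. = FALSE)
  lev <- pmin(255L, pmax(0L, as.integer(round(v * 255))))
  if (length(unique(lev)) < 2L)
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  h <- tabulate(lev + 1L, 256L)
  p <- h / sum(h)
  vals <- (0:255) / 255
  w0 <- cumsum(p)
  m0 <- cumsum(p * vals)
  mt <- m0[256]
  # between-class variance for split {<= k}, {> k}; maximizing it minimizes
  # the within-class variance
  bc <- ifelse(w0 > 0 & w0 < 1, (mt * w0 - m0)^2 / (w0 * (1 - w0)), -Inf)
  bc[256] <- -Inf
  k <- which.max(bc) - 1L  # which.max takes the first (lowest) maximum
  (k + 0.5) / 255
}

#' Label connected regions
#'
#' 8-connected component labeling of a binary mask, optionally discarding
#' regions below a minimum area (labels are then compacted to `1..K`).
#'
#' @param mask a logical matrix.
#' @param min_area discard regions smaller than this many pixels (default 1).
#' @return an integer H x W label matrix, 0 = background.
#' @export
label_regions <- function(mask, min_area = 1) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  lab <- label_components_cpp(mask, 8L)
  k <- max(lab)
  if (k == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], k)
  keep <- which(sizes >= min_area)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Classify candidate-region pixels as white or gray
#'
#' For each labeled candidate region, the region is dilated by
#' `dilation_radius` to include its immediate surroundings, and pixels in
#' the dilated area are split by the Otsu cut of the local luminance patch:
#' *white* (lumen-like, above the cut) versus *gray* (stained tissue, below).
#' Near-constant patches fall back to the global luminance threshold.
#'
#' @param img an H x W x 3 RGB array.
#' @param labels an integer label matrix from [label_regions()].
#' @param dilation_radius Euclidean dilation radius in pixels (default 5).
#' @return a data.frame with one row per region: `label`, `area_px`
#'   (undilated region area), `white_px`, `gray_px` (counts over the dilated
#'   area).
#' @export
classify_pixels <- function(img, labels, dilation_radius = 5) {
  assert_rgb(img)
  lum <- luminance(img)
  k <- max(labels)
  glob <- tryCatch(otsu_threshold(lum), error = function(e) 0.5)
  out <- data.frame(label = integer(0), area_px = integer(0),
                    white_px = integer(0), gray_px = integer(0))
  for (r in seq_len(k)) {
    m <- labels == r
    dm <- dilate_mask(m, dilation_radius)
    vals <- lum[dm]
    thr <- tryCatch(otsu_threshold(vals), error = function(e) glob)
    w <- sum(vals > thr)
    out <- rbind(out, data.frame(label = r, area_px = sum(m),
                                 white_px = w, gray_px = sum(dm) - w))
  }
  out
}

#' Spatiochromatic region type
#'
#' Bands a candidate region into one of five types by its white (lumen)
#' fraction `w = white_px / (white_px + gray_px)`:
#' Type 1 (all white), Type 2 (almost white / few gray), Type 3 (half and
#' half — the classic vessel pattern of a pale lumen inside a stained wall),
#' Type 4 (few white / almost all gray), Type 5 (no white, all gray).
#'
#' @param white_px,gray_px pixel counts (their sum must be positive).
#' @param cuts four strictly increasing band cuts in `(0, 1)`; defaults
#'   `c(0.05, 0.35, 0.65, 0.95)`.
#' @return an integer type in `1:5`.
#' @export
region_type <- function(white_px, gray_px, cuts = c(0.05, 0.35, 0.65, 0.95)) {
  if (length(cuts) != 4L || any(diff(cuts) <= 0) || cuts[1] <= 0 || cuts[4] >= 1)
    stop("cuts must be four strictly increasing values in (0,1)", call. = FALSE)
  if (white_px + gray_px < 1) stop("empty region", call. = FALSE)
  w <- white_px / (white_px + gray_px)
  if (w > cuts[4]) 1L
  else if (w > cuts[3]) 2L
  else if (w > cuts[2]) 3L
  else if (w > cuts[1]) 4L
  else 5L
}

#' SAR / AIR aspect-ratio test
#'
#' Applies the three acceptance criteria to typed candidate regions:
#' \enumerate{
#'   \item a Type 5 region (all gray, no white) is assigned `SAR = 1` and
#'     becomes background outright;
#'   \item the surrounding area ratio `SAR = gray_px / area_px` measures how
#'     much stained tissue surrounds (and composes) the candidate relative
#'     to its area;
#'   \item the area image ratio `AIR = area_px / image_size` discards
#'     implausibly large candidates.
#' }
#' A region is accepted as vessel when `SAR` lies inside `sar_band` and
#' `AIR <= air_max`. Note that `SAR = 1` — the Type 5 background
#' convention — lies *outside* the default band, so solid stained clutter
#' (whose dilated area is essentially all gray) is rejected. Type 3 regions
#' (half white / half gray) are additionally flagged `needs_refinement`: the
#' pattern the test exists to isolate, routed to [refine_region()].
#'
#' @param records a data.frame with columns `label`, `area_px`, `white_px`,
#'   `gray_px`, `type`.
#' @param image_size total pixel count of the image (positive).
#' @param sar_band numeric `c(low, high)` acceptance band for SAR
#'   (default `c(0.12, 0.88)`).
#' @param air_max maximum AIR (default 0.2).
#' @return `records` with columns `sar`, `air`, `accepted`,
#'   `needs_refinement` added.
#' @export
aspect_ratio_test <- function(records, image_size, sar_band = c(0.12, 0.88),
                              air_max = 0.2) {
  if (image_size <= 0) stop("image_size must be positive", call. = FALSE)
  stopifnot(all(c("area_px", "white_px", "gray_px", "type") %in%
                  names(records)))
  sar <- ifelse(records$type == 5L, 1,
                records$gray_px / pmax(records$area_px, 1L))
  air <- records$area_px / image_size
  records$sar <- sar
  records$air <- air
  records$accepted <- records$type != 5L &
    sar >= sar_band[1] & sar <= sar_band[2] & air <= air_max
  records$needs_refinement <- records$type == 3L
  records
}

#' Refine a candidate region by local adaptive thresholding
#'
#' Re-segments a flagged (Type 3) candidate inside its padded bounding box:
#' Niblack local thresholding on luminance marks stained (wall) pixels,
#' speckle components below `min_speck` are dropped, enclosed holes below
#' `min_hole` (the lumen) are filled, and only components overlapping the
#' original candidate are kept. Regions not flagged for refinement are
#' returned unchanged. The caller re-types and re-tests the refined region
#' exactly once; there is no refinement loop.
#'
#' @param img an H x W x 3 RGB array.
#' @param mask logical matrix: the candidate's current mask.
#' @param needs_refinement flag from [aspect_ratio_test()]; if `FALSE` the
#'   mask is returned as-is.
#' @param niblack_k,niblack_radius Niblack parameters (defaults -0.2, 7).
#' @param dilation_radius bounding-box pad and allowed growth radius
#'   (default 5).
#' @param min_hole fill enclosed holes smaller than this (default 10000).
#' @param min_speck drop stained speckles smaller than this (default 10).
#' @return a list with logical matrices `mask` (refined region), `wall`
#'   (stained pixels) and `lumen` (filled interior).
#' @export
refine_region <- function(img, mask, needs_refinement = TRUE,
                          niblack_k = -0.2, niblack_radius = 7,
                          dilation_radius = 5, min_hole = 10000,
                          min_speck = 10) {
  assert_rgb(img)
  if (!isTRUE(needs_refinement))
    return(list(mask = mask, wall = mask & FALSE, lumen = mask & FALSE))
  lum <- luminance(img)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(mask = mask, wall = mask, lumen = mask))
  H <- nrow(mask); W <- ncol(mask)
  r1 <- max(1L, min(idx[, 1]) - dilation_radius)
  r2 <- min(H, max(idx[, 1]) + dilation_radius)
  c1 <- max(1L, min(idx[, 2]) - dilation_radius)
  c2 <- min(W, max(idx[, 2]) + dilation_radius)
  patch <- lum[r1:r2, c1:c2, drop = FALSE]
  rad <- min(niblack_radius, (min(dim(patch)) - 1L) %/% 2L)
  refined <- mask & FALSE
  wall_full <- refined
  if (rad >= 1L) {
    surf <- niblack_surface(patch, rad, niblack_k)
    wall <- patch < surf$t
    allowed <- dilate_mask(mask, dilation_radius)[r1:r2, c1:c2, drop = FALSE]
    wall <- wall & allowed
    lab <- label_regions(wall, min_area = min_speck)
    wall <- lab > 0L
    filled <- fill_holes(wall, min_hole)
    # keep only components that overlap the original candidate
    flab <- label_regions(filled)
    keep <- unique(flab[mask[r1:r2, c1:c2, drop = FALSE] & flab > 0L])
    filled <- flab %in% keep & flab > 0L
    refined[r1:r2, c1:c2] <- matrix(filled, r2 - r1 + 1L)
    wall_full[r1:r2, c1:c2] <- wall
  }
  if (!any(refined))
    return(list(mask = mask, wall = mask, lumen = mask & FALSE))
  list(mask = refined, wall = wall_full & refined,
       lumen = refined & !(wall_full & refined))
}

#' Vessel segmentation pipeline
#'
#' The full two-stage segmentation flow. Stage one derives a preliminary
#' vessel/background partition: BT.601 luminance, sigmoid contrast
#' enhancement against light bias, and GPAC curve evolution
#' ([gpac_evolve()]); the stained (darker) phase, hole-filled, yields the
#' candidate regions. Stage two discriminates: 8-connected candidate
#' labeling, white/gray pixel classification against local Otsu cuts
#' ([classify_pixels()]), spatiochromatic typing ([region_type()]), the
#' SAR/AIR aspect-ratio test ([aspect_ratio_test()]), and one Niblack
#' refinement pass for Type 3 regions ([refine_region()]) followed by a
#' single re-type and re-test. The final mask is the union of accepted
#' (possibly refined) regions. Deterministic for a fixed configuration.
#'
#' @param img an H x W x 3 RGB array in `[0, 1]`.
#' @param config a [vesselab_config()] list.
#' @return an object of class `vessel_segmentation`: list with `mask`
#'   (logical, accepted vessels), `labels` (final accepted-region label
#'   map), `candidates` (candidate label map before the test), `records`
#'   (data.frame: `label`, `area_px`, `white_px`, `gray_px`, `type`, `sar`,
#'   `air`, `accepted`, `needs_refinement`, `refined`), `contour` (the final
#'   GPAC state) and `config`.
#' @export
segment_pipeline <- function(img, config = vesselab_config()) {
  assert_rgb(img)
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("segment_pipeline [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  feat <- stage("enhance", {
    sigmoid_enhance(luminance(img), cfg$sigmoid$gain, cfg$sigmoid$midpoint)
  })
  st <- stage("gpac", {
    init <- initialize_contour(dim(feat), cfg$gpac$init_mode, feature = feat,
                               seed = cfg$gpac$seed)
    gpac_evolve(feat, init, cfg$gpac$block_size, cfg$gpac$curvature_weight,
                cfg$gpac$max_iters, cfg$gpac$tol)
  })
  candidates <- stage("candidates", {
    inside <- st$phi > 0
    stained <- if (mean(feat[inside]) <= mean(feat[!inside])) inside else !inside
    stained <- fill_holes(stained, cfg$regions$min_hole)
    label_regions(stained, cfg$regions$min_area)
  })
  records <- stage("classify", {
    cp <- classify_pixels(img, candidates, cfg$regions$dilation_radius)
    if (nrow(cp)) {
      cp$type <- vapply(seq_len(nrow(cp)), function(i)
        region_type(cp$white_px[i], cp$gray_px[i],
                    cfg$regions$white_fraction_cuts), integer(1))
      aspect_ratio_test(cp, length(feat),
                        c(cfg$regions$sar_low, cfg$regions$sar_high),
                        cfg$regions$air_max)
    } else {
      cbind(cp, type = integer(0), sar = numeric(0), air = numeric(0),
            accepted = logical(0), needs_refinement = logical(0))
    }
  })
  records$refined <- FALSE
  masks <- lapply(seq_len(nrow(records)),
                  function(i) candidates == records$label[i])
  for (i in seq_len(nrow(records))) {
    if (!records$needs_refinement[i]) next
    rf <- stage("refine", refine_region(
      img, masks[[i]], TRUE, cfg$niblack$k,
      min(cfg$niblack$window_radius, 7), cfg$regions$dilation_radius,
      cfg$regions$min_hole))
    if (!identical(rf$mask, masks[[i]])) {
      masks[[i]] <- rf$mask
      records$refined[i] <- TRUE
      # re-classify, re-type and re-test once on the refined mask
      lab1 <- matrix(0L, nrow(rf$mask), ncol(rf$mask))
      lab1[rf$mask] <- 1L
      cp <- classify_pixels(img, lab1, cfg$regions$dilation_radius)
      records$area_px[i] <- cp$area_px[1]
      records$white_px[i] <- cp$white_px[1]
      records$gray_px[i] <- cp$gray_px[1]
      records$type[i] <- region_type(cp$white_px[1], cp$gray_px[1],
                                     cfg$regions$white_fraction_cuts)
      rt <- aspect_ratio_test(records[i, , drop = FALSE], length(feat),
                              c(cfg$regions$sar_low, cfg$regions$sar_high),
                              cfg$regions$air_max)
      records$sar[i] <- rt$sar
      records$air[i] <- rt$air
      records$accepted[i] <- rt$accepted
    }
  }
  mask <- matrix(FALSE, nrow(feat), ncol(feat))
  labels <- matrix(0L, nrow(feat), ncol(feat))
  nxt <- 0L
  for (i in seq_len(nrow(records))) {
    if (!records$accepted[i]) next
    nxt <- nxt + 1L
    mask <- mask | masks[[i]]
    labels[masks[[i]]] <- nxt
  }
  structure(list(mask = mask, labels = labels, candidates = candidates,
                 records = records, contour = st, config = cfg),
            class = "vessel_segmentation")
}
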