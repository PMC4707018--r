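#' Vessel count error
#'
#' XOR-style count mismatch against ground truth, as a percentage of the
#' true vessel number. Predicted 8-connected regions are greedily matched to
#' ground-truth vessels by intersection-over-union (IoU, threshold 0.3,
#' best matches first); the error counts every unmatched prediction and
#' every unmatched truth region:
#' \deqn{\mathrm{error} = \frac{\#\{\mathrm{unmatched\ pred}\} +
#'   \#\{\mathrm{unmatched\ GT}\}}{N_{GT}} \times 100\%.}
#' When predictions and truth are spatially disjoint region sets this
#' reduces to `|N_pred - N_GT| / N_GT * 100` plus the doubly-counted
#' mismatches; a perfect prediction scores 0.
#'
#' @param pred_mask logical matrix of predicted vessel pixels, or an integer
#'   label matrix.
#' @param truth a ground-truth list with `n_vessels` and `per_vessel_masks`
#'   (as produced by [generate_vessel_image()]).
#' @param iou_min minimum IoU for a match (default 0.3).
#' @return the count error in percent (>= 0).
#' @export
count_error <- function(pred_mask, truth, iou_min = 0.3) {
  if (is.null(truth$n_vessels) || truth$n_vessels < 1)
    stop("empty ground truth", call. = FALSE)
  labels <- if (is.logical(pred_mask)) label_regions(pred_mask) else pred_mask
  np <- max(labels)
  ng <- truth$n_vessels
  if (np == 0L) return(100)  # every ground-truth vessel is unmatched
  iou <- matrix(0, np, ng)
  for (g in seq_len(ng)) {
    gm <- truth$per_vessel_masks[[g]]
    for (p in seq_len(np)) {
      pm <- labels == p
      inter <- sum(pm & gm)
      if (inter > 0) iou[p, g] <- inter / sum(pm | gm)
    }
  }
  matched_p <- logical(np); matched_g <- logical(ng)
  repeat {
    iou[matched_p, ] <- -1
    iou[, matched_g] <- -1
    best <- which.max(iou)
    if (iou[best] < iou_min) break
    p <- (best - 1) %% np + 1
    g <- (best - 1) %/% np + 1
    matched_p[p] <- TRUE; matched_g[g] <- TRUE
    if (all(matched_p) || all(matched_g)) break
  }
  100 * (sum(!matched_p) + sum(!matched_g)) / ng
}

#' Pixel area error
#'
#' XOR (symmetric-difference) pixel error relative to ground truth:
#' \deqn{\mathrm{error} = \frac{|\mathrm{pred} \oplus \mathrm{GT}|}
#'   {|\mathrm{GT}|} \times 100\%.}
#' Zero iff the masks are identical; the denominator is always the
#' ground-truth area, so the measure is not symmetric in its arguments.
#'
#' @param pred_mask,gt_mask logical matrices of equal shape; `gt_mask` must
#'   have at least one foreground pixel.
#' @return the area error in percent (>= 0, can exceed 100).
#' @export
area_error <- function(pred_mask, gt_mask) {
  stopifnot(identical(dim(pred_mask), dim(gt_mask)))
  ng <- sum(gt_mask)
  if (ng == 0) stop("empty ground-truth mask", call. = FALSE)
  100 * sum(xor(pred_mask, gt_mask)) / ng
}

#' Fuzzy c-means pixel clustering
#'
#' Soft clustering of per-pixel features (RGB channels for a color image,
#' intensity for a plane) into `n_classes` clusters by fuzzy c-means
#' (delegated to [e1071::cmeans()]). Centers are initialized at evenly
#' spaced luminance quantiles of the data, which is deterministic and keeps
#' small classes (thin stained walls) from being absorbed by a dominant
#' background. The *vessel* cluster is resolved deterministically from
#' `stain_color` as the luminance extreme on the stain's side — the darkest
#' centroid for a dark stain — rather than by arbitrary cluster index; this
#' ordering survives the monotone luminance transforms the filtering
#' pipeline applies, while absolute color proximity does not.
#'
#' @param img an H x W x 3 RGB array or an H x W matrix.
#' @param n_classes number of clusters (default 3).
#' @param fuzzifier fuzziness exponent `m > 1` (default 2).
#' @param seed integer seed for the initialization (default 1).
#' @param stain_color reference color (or scalar intensity) of the stain
#'   (default `c(0.45, 0.30, 0.20)`).
#' @return a list of class `fcm_result`: `labels` (H x W integer map),
#'   `centers`, `vessel_class` (index), `vessel_mask` (logical matrix).
#' @export
fcm_cluster <- function(img, n_classes = 3, fuzzifier = 2, seed = 1L,
                        stain_color = c(0.45, 0.30, 0.20)) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (is.array(img) && length(dim(img)) == 3L) {
    d <- dim(img)
    x <- matrix(img, d[1] * d[2], d[3])
    shp <- d[1:2]
  } else {
    x <- matrix(as.numeric(img), length(img), 1L)
    shp <- dim(img)
    stain_color <- stain_color[1]
  }
  # deterministic initialization: centers start at pixels drawn from evenly
  # spaced luminance quantiles, so minority classes (the thin stained walls)
  # are represented from the outset
  lum_w <- if (ncol(x) >= 3L) c(0.299, 0.587, 0.114) else 1
  px_y <- as.numeric(x %*% lum_w)
  qs <- quantile(px_y, probs = seq(0.02, 0.98, length.out = n_classes),
                 names = FALSE, type = 1)
  init_idx <- vapply(qs, function(q) which.min(abs(px_y - q)), integer(1))
  init <- x[init_idx, , drop = FALSE]
  if (anyDuplicated(init))
    init <- init + with_seed(seed, matrix(rnorm(length(init), 0, 1e-3),
                                          nrow(init)))
  fit <- with_seed(seed,
                   e1071::cmeans(x, centers = init, m = fuzzifier,
                                 iter.max = 300, verbose = FALSE))
  labels <- matrix(as.integer(fit$cluster), shp[1], shp[2])
  centers <- fit$centers
  # the vessel cluster is the luminance extreme on the stain's side: the
  # darkest centroid for a dark stain (the usual IHC case), the brightest
  # for a pale one. Monotone luminance transforms (sigmoid enhancement,
  # multiplicative recombination, quantization) preserve this ordering,
  # which absolute color proximity does not survive.
  cen_y <- as.numeric(centers %*% lum_w)
  stain_y <- sum(stain_color[seq_along(lum_w)] * lum_w)
  vc <- if (stain_y < 0.5) which.min(cen_y) else which.max(cen_y)
  structure(list(labels = labels, centers = centers,
                 vessel_class = as.integer(vc),
                 vessel_mask = labels == vc),
            class = "fcm_result")
}

#' Filtering-benefit benchmark
#'
#' Re-establishes, on the synthetic suite, the direction that salient-region
#' filtering improves downstream clustering-based segmentation: each image
#' is segmented by three-class fuzzy c-means twice — once raw, once after
#' [filter_pipeline()] — the vessel cluster is hole-filled, and the XOR area
#' error against ground truth is reported for both.
#'
#' @param suite a `vessel_suite` from [generate_suite()].
#' @param config a [vesselab_config()] list.
#' @param seed seed for the clustering initializations (default
#'   `config$seed`).
#' @param stain_color reference stain color for vessel-cluster selection.
#' @return a data.frame with columns `image_id`, `error_unfiltered_pct`,
#'   `error_filtered_pct`.
#' @export
filtering_benefit_experiment <- function(suite, config = vesselab_config(),
                                         seed = config$seed,
                                         stain_color = c(0.45, 0.30, 0.20)) {
  stopifnot(inherits(suite, "vessel_suite"), length(suite$images) >= 1)
  rows <- lapply(seq_along(suite$images), function(i) {
    item <- suite$images[[i]]
    err <- function(img) {
      fc <- fcm_cluster(img, 3, 2, seed = seed + i, stain_color = stain_color)
      m <- fill_holes(fc$vessel_mask, Inf)
      area_error(m, item$truth$vessel_mask)
    }
    filt <- filter_pipeline(item$image, config)
    data.frame(image_id = suite$manifest$id[i],
               error_unfiltered_pct = err(item$image),
               error_filtered_pct = err(filt))
  })
  do.call(rbind, rows)
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper computing both metrics for one image.
#'
#' @param seg a `vessel_segmentation` or a logical mask.
#' @param truth a ground-truth list (see [generate_vessel_image()]).
#' @return a list of class `vessel_eval` with `count_error_pct`,
#'   `area_error_pct`, `n_gt`, `n_pred`.
#' @export
evaluate_segmentation <- function(seg, truth) {
  mask <- if (inherits(seg, "vessel_segmentation")) seg$mask else seg
  labels <- if (inherits(seg, "vessel_segmentation")) seg$labels
            else label_regions(mask)
  structure(list(count_error_pct = count_error(labels, truth),
                 area_error_pct = area_error(mask, truth$vessel_mask),
                 n_gt = truth$n_vessels, n_pred = max(labels)),
            class = "vessel_eval")
}
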