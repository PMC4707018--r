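#' @export
print.vessel_segmentation <- function(x, ...) {
  n_acc <- sum(x$records$accepted)
  cat("Vessel segmentation: ", nrow(x$records), " candidate region(s), ",
      n_acc, " accepted as vessel\n", sep = "")
  cat("  image: ", nrow(x$mask), " x ", ncol(x$mask),
      "; vessel pixels: ", sum(x$mask), "\n", sep = "")
  cat("  GPAC: ", x$contour$iteration, " iteration(s)",
      if (x$contour$converged) ", converged" else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.vessel_segmentation <- function(object, ...) {
  cat("Vessel segmentation summary\n")
  print(object)
  if (nrow(object$records)) {
    cat("\nPer-region records:\n")
    print(object$records, row.names = FALSE, digits = 3)
  }
  invisible(object$records)
}

#' @export
plot.vessel_segmentation <- function(x, img = NULL, ...) {
  H <- nrow(x$mask); W <- ncol(x$mask)
  base <- if (!is.null(img)) img else
    array(rep(0.5 * (x$candidates > 0) + 0.3, 3L), c(H, W, 3L))
  over <- base
  over[, , 1][x$mask] <- 1
  over[, , 2][x$mask] <- 0.2 + 0.5 * over[, , 2][x$mask]
  over[, , 3][x$mask] <- 0.2 * over[, , 3][x$mask]
  plot_rgb(over, main = "accepted vessel regions (highlighted)")
  invisible(x)
}

#' @export
print.vessel_synth <- function(x, ...) {
  cat("Synthetic IHC vessel image: ", x$spec$height, " x ", x$spec$width,
      ", ", x$truth$n_vessels, " vessel(s), clutter ",
      x$spec$clutter_density, ", noise sd ", x$spec$noise_sigma, "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.vessel_synth <- function(x, what = c("image", "mask"), ...) {
  what <- match.arg(what)
  if (what == "image") plot_rgb(x$image, main = "synthetic IHC image")
  else plot_rgb(array(rep(x$truth$vessel_mask, 3L),
                      c(dim(x$truth$vessel_mask), 3L)),
                main = "ground-truth vessel mask")
  invisible(x)
}

#' @export
print.vessel_eval <- function(x, ...) {
  cat("Segmentation evaluation: count error ",
      format(x$count_error_pct, digits = 4), "% (", x$n_pred, " predicted / ",
      x$n_gt, " true); area error ", format(x$area_error_pct, digits = 4),
      "%\n", sep = "")
  invisible(x)
}

# raster display of an H x W x 3 array
plot_rgb <- function(img, main = "") {
  op <- par(mar = c(1, 1, 2, 1))
  on.exit(par(op))
  plot.new()
  plot.window(c(0, ncol(img)), c(0, nrow(img)), asp = 1)
  rasterImage(img, 0, 0, ncol(img), nrow(img), interpolate = FALSE)
  title(main)
  invisible(NULL)
}
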