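#' Default configuration
#'
#' Returns the complete, fully materialized configuration used by the
#' filtering and segmentation pipelines. Every key can be overridden either
#' programmatically (`modifyList`-style via `...`) or from a YAML file with
#' [load_config()]. Unknown keys are rejected.
#'
#' Key groups (defaults in parentheses):
#' \describe{
#'   \item{gaussian}{`lambda0` (520), `sigma_lambda` (55) — metadata for the
#'     Gaussian color model; the fixed matrix is used regardless.}
#'   \item{normalized}{`epsilon` (1e-6) — guard for \eqn{\hat E \approx 0}.}
#'   \item{niblack}{`k` (-0.2), `window_radius` (15).}
#'   \item{sigmoid}{`gain` (10), `midpoint` ("otsu").}
#'   \item{bilateral}{`sigma_s` (3), `sigma_r` (0.2), `window_radius` (7).}
#'   \item{detail}{`n_iters` (2), `gain` (1).}
#'   \item{quant}{`n_bins` (8), `kappa_q` (NULL = `8 / Delta_q`).}
#'   \item{filter}{`neutral_large_scale`, `neutral_detail` (FALSE) —
#'     diagnostic switches replacing a layer by the neutral factor 1.}
#'   \item{gpac}{`block_size` (4), `curvature_weight` (0.5), `max_iters`
#'     (300), `tol` (0.001), `init_mode` ("threshold_seed"), `seed` (1).}
#'   \item{regions}{`dilation_radius` (5), `white_fraction_cuts`
#'     (0.05, 0.35, 0.65, 0.95), `sar_low` (0.12), `sar_high` (0.88),
#'     `air_max` (0.2), `min_area` (20), `min_hole` (10000).}
#'   \item{seed}{global seed for randomized stages (1).}
#' }
#'
#' @param ... named overrides, e.g. `niblack = list(k = -0.3)`.
#' @return a nested list of class `vesselab_config`.
#' @export
vesselab_config <- function(...) {
  cfg <- list(
    version = "1",
    seed = 1L,
    gaussian = list(lambda0 = 520, sigma_lambda = 55),
    normalized = list(epsilon = 1e-6),
    niblack = list(k = -0.2, window_radius = 15),
    sigmoid = list(gain = 10, midpoint = "otsu"),
    bilateral = list(sigma_s = 3, sigma_r = 0.2, window_radius = 7),
    detail = list(n_iters = 2, gain = 1),
    quant = list(n_bins = 8, kappa_q = NULL),
    filter = list(neutral_large_scale = FALSE, neutral_detail = FALSE),
    gpac = list(block_size = 4, curvature_weight = 0.5, max_iters = 300,
                tol = 0.001, init_mode = "threshold_seed", seed = 1L),
    regions = list(dilation_radius = 5,
                   white_fraction_cuts = c(0.05, 0.35, 0.65, 0.95),
                   sar_low = 0.12, sar_high = 0.88, air_max = 0.2,
                   min_area = 20, min_hole = 10000)
  )
  over <- list(...)
  if (length(over)) cfg <- merge_config(cfg, over)
  structure(cfg, class = "vesselab_config")
}

# recursive merge with unknown-key rejection; `quant$kappa_q` may go
# from NULL to a number, so use explicit key checks rather than modifyList
merge_config <- function(base, over, path = character()) {
  if (is.null(names(over)) || any(names(over) == ""))
    stop("configuration overrides must be named", call. = FALSE)
  for (key in names(over)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(over[[key]]))
        stop("configuration key ", full, " must be a named list", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], over[[key]], c(path, key))
    } else {
      base[key] <- over[key]
    }
  }
  base
}

#' Load a configuration from YAML
#'
#' Reads a YAML file of overrides, merges it over the defaults of
#' [vesselab_config()] and returns the complete effective configuration.
#' Unknown keys are rejected by name, so typos fail loudly.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a `vesselab_config` list with every key materialized.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(vesselab_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(vesselab_config())
  do.call(vesselab_config, over)
}

#' @export
print.vesselab_config <- function(x, ...) {
  cat("vesselab configuration (schema ", x$version, ")\n", sep = "")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
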