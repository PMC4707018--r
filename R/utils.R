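# internal helpers shared across modules

# validate an H x W x 3 RGB array in [0,1]
assert_rgb <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

assert_plane <- function(x, what = "x") {
  if (!is.matrix(x)) stop(what, " must be a matrix", call. = FALSE)
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

clip01 <- function(x) {
  x[] <- pmin(1, pmax(0, x))
  x
}

# min-max rescale to [0,1]; constant input maps to `const`
normalize01 <- function(x, const = 1) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) {
    x[] <- const
    return(x)
  }
  (x - r[1]) / (r[2] - r[1])
}

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# binary dilation by Euclidean radius r, via distance transform
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  storage.mode(mask) <- "integer"
  d <- EBImage::distmap(1L - mask)
  m <- d <= radius
  storage.mode(m) <- "logical"
  matrix(m, nrow(mask), ncol(mask))
}

# signed Euclidean distance: positive inside `mask`
signed_distance <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(1L - m))
  din - dout
}

# fill enclosed background holes of area < min_hole in a binary mask
fill_holes <- function(mask, min_hole = Inf) {
  bg <- !mask
  lab <- label_components_cpp(bg, 4L)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  sizes <- tabulate(lab[lab > 0L])
  holes <- setdiff(which(sizes < min_hole), border)
  if (length(holes)) mask[lab %in% holes] <- TRUE
  mask
}
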