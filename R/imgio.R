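#' Read an RGB image
#'
#' Reads a PNG or TIFF (8- or 16-bit; 1, 3 or 4 channels) into an
#' H x W x 3 array normalized to `[0, 1]`. Grayscale images are replicated
#' across channels; an alpha channel is dropped with a warning.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return an H x W x 3 numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE))
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  nch <- dim(raw)[3]
  if (nch == 2L) {
    warning("dropping alpha channel of grayscale image: ", path)
    raw <- array(rep(raw[, , 1], 3L), c(dim(raw)[1:2], 3L))
  } else if (nch == 4L) {
    warning("dropping alpha channel: ", path)
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (nch != 3L) {
    stop("unsupported channel count (", nch, "): ", path, call. = FALSE)
  }
  clip01(raw)
}

#' Write an RGB image as PNG
#'
#' Values are clipped to `[0, 1]`; 8-bit quantization happens at write time.
#'
#' @param img an H x W x 3 array in `[0, 1]`.
#' @param path output path (`.png`).
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0 / 255)
#'
#' @param mask a logical (or 0/1) matrix.
#' @param path output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask (foreground = value > 0.5)
#'
#' @param path path to a PNG or TIFF mask file.
#' @return a logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  img[, , 1] > 0.5
}
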