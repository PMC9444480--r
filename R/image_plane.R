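#' Validate and normalize a grayscale image plane
#'
#' Images throughout the package are plain numeric matrices with intensities
#' in \[0, 1\], rows indexed top-to-bottom and columns left-to-right. This
#' helper validates a matrix (or coerces an array with a singleton third
#' dimension) and optionally rescales integer-valued data onto \[0, 1\].
#'
#' @param x numeric matrix, or array whose third dimension has length 1.
#' @param rescale one of `"none"` (require values already in \[0, 1\]),
#'   `"auto"` (divide by 255 or 65535 when the data look like 8/16-bit
#'   integers), `"range"` (affinely map \[min, max\] to \[0, 1\]).
#' @return a numeric matrix with all values finite and inside \[0, 1\].
#' @export
as_image_plane <- function(x, rescale = c("none", "auto", "range")) {
  rescale <- match.arg(rescale)
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] == 1L) x <- x[, , 1L] else
      stopf("expected a grayscale image; got %d channels", dim(x)[3])
  }
  if (!is.matrix(x) || !is.numeric(x))
    stopf("an image plane must be a numeric matrix")
  if (!all(is.finite(x))) stopf("image contains non-finite values")
  if (rescale == "auto") {
    mx <- max(x)
    if (mx > 1) x <- if (mx <= 255) x / 255 else x / 65535
  } else if (rescale == "range") {
    rg <- range(x)
    x <- if (rg[2] > rg[1]) (x - rg[1]) / (rg[2] - rg[1]) else x * 0
  }
  if (min(x) < 0 || max(x) > 1)
    stopf("image intensities must lie in [0, 1] (got range [%g, %g])",
          min(x), max(x))
  x
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8- and 16-bit files are normalized to \[0, 1\] on load; floating-point
#' TIFF data are passed through (and must already be in \[0, 1\]). RGB(A)
#' input is converted to luminance by channel averaging.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return an image plane (numeric matrix in \[0, 1\]).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (use PNG or TIFF)", ext))
  if (length(dim(img)) == 3) {
    k <- min(dim(img)[3], 3L)        # drop alpha, average color channels
    img <- apply(img[, , seq_len(k), drop = FALSE], c(1, 2), mean)
  }
  as_image_plane(img)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img image plane in \[0, 1\].
#' @param path output path; the extension selects the format. PNG is written
#'   8-bit; TIFF is written as 32-bit float (lossless for test fixtures).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_image_plane(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L,
                           reduce = FALSE),
    stopf("unsupported image format '%s' (use PNG or TIFF)", ext))
  invisible(path)
}
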