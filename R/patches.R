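#' Gradient feature operator
#'
#' The four stencils used to lift a low-resolution (mid) image into the
#' feature space in which it is sparse-coded: first- and second-order
#' derivative filters in the horizontal and vertical directions, capturing
#' edge and texture detail. Each stencil sums to zero, so responses vanish
#' on constant images. Responses are computed by correlation (the stencil is
#' not flipped) with replicate padding at the borders.
#'
#' @param taps list of four numeric matrices (stencils). The default is the
#'   standard choice for coupled-dictionary super-resolution:
#'   `f1 = c(-1, 0, 1)` (horizontal), `f2 = t(f1)`, `f3 = c(1, 0, -2, 0, 1)`,
#'   `f4 = t(f3)`.
#' @return an object of class `feature_operator`.
#' @export
feature_operator <- function(taps = NULL) {
  if (is.null(taps)) {
    f1 <- matrix(c(-1, 0, 1), nrow = 1)
    f3 <- matrix(c(1, 0, -2, 0, 1), nrow = 1)
    taps <- list(f1, t(f1), f3, t(f3))
  }
  if (!is.list(taps) || length(taps) != 4L)
    stopf("taps must be a list of four stencil matrices")
  taps <- lapply(taps, function(f) {
    f <- as.matrix(f)
    if (!all(is.finite(f))) stopf("stencil entries must be finite")
    if (abs(sum(f)) > 1e-12)
      stopf("each stencil must sum to 0 (zero response on constants)")
    f
  })
  structure(list(taps = taps, pad = "replicate"), class = "feature_operator")
}

# 2-D correlation of `img` with stencil `f` (odd-sized in each dimension),
# replicate padding. Vectorized as a sum of shifted copies.
correlate2d <- function(img, f) {
  fr <- nrow(f); fc <- ncol(f)
  cr <- (fr - 1L) %/% 2L; cc <- (fc - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(fr)) {
    for (j in seq_len(fc)) {
      wgt <- f[i, j]
      if (wgt == 0) next
      rows <- pmin(pmax(seq_len(h) + (i - 1L - cr), 1L), h)
      cols <- pmin(pmax(seq_len(w) + (j - 1L - cc), 1L), w)
      out <- out + wgt * img[rows, cols, drop = FALSE]
    }
  }
  out
}

#' Gradient feature stack of a mid image
#'
#' Applies the four stencils of a [feature_operator()] to the bicubic
#' upscaled low-resolution image (the mid image, already on the
#' high-resolution pixel grid), returning four same-size response planes.
#'
#' @param mid_image image plane (mid image).
#' @param op a [feature_operator()].
#' @return list of four numeric matrices, same dimensions as `mid_image`.
#' @export
lr_features <- function(mid_image, op = feature_operator()) {
  if (!inherits(op, "feature_operator")) stopf("op must be a feature_operator")
  if (!is.matrix(mid_image) || !is.numeric(mid_image))
    stopf("mid_image must be a numeric matrix")
  lapply(op$taps, function(f) correlate2d(mid_image, f))
}

# 0-based anchors along one axis: multiples of the stride, plus a final
# flush-to-border anchor when the last regular one does not reach the edge.
axis_anchors <- function(n, patch, stride) {
  last <- n - patch
  a <- seq.int(0L, last, by = stride)
  if (a[length(a)] != last) a <- c(a, last)
  a
}

#' Extract overlapping patches
#'
#' Slices an image into overlapping square patches on a regular grid.
#' Anchors (top-left corners, 0-based) sit at multiples of the stride
#' `patch_size - overlap`; a flush-to-border anchor is appended per axis when
#' needed so every pixel is covered. Each patch is vectorized in row-major
#' raster order into one column of the patch matrix.
#'
#' @param image image plane (any numeric matrix).
#' @param patch_size patch side length in pixels.
#' @param overlap overlap between adjacent patches, `0 <= overlap < patch_size`.
#' @return an object of class `patch_grid`: list with `patches`
#'   (`patch_size^2 x n` matrix), `positions` (`n x 2` matrix of 0-based
#'   (row, col) anchors, row-major order), `patch_size`, `overlap`, `stride`,
#'   `image_dim`.
#' @seealso [assemble_patches()]
#' @export
extract_patches <- function(image, patch_size, overlap) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a numeric matrix")
  patch_size <- as.integer(patch_size); overlap <- as.integer(overlap)
  if (overlap < 0 || overlap >= patch_size)
    stopf("overlap must satisfy 0 <= overlap < patch_size")
  if (patch_size > min(dim(image)))
    stopf("patch_size %d exceeds image dimensions %dx%d",
          patch_size, nrow(image), ncol(image))
  stride <- patch_size - overlap
  ar <- axis_anchors(nrow(image), patch_size, stride)
  ac <- axis_anchors(ncol(image), patch_size, stride)
  # row-major ordering of anchor pairs: row varies slowest
  pos <- cbind(rep(ar, each = length(ac)), rep(ac, times = length(ar)))
  n <- nrow(pos)
  P <- matrix(0, patch_size^2, n)
  # within-patch raster is row-major: offset (dr, dc) -> index dr*p + dc + 1
  for (dr in 0:(patch_size - 1L)) {
    for (dc in 0:(patch_size - 1L)) {
      P[dr * patch_size + dc + 1L, ] <-
        image[cbind(pos[, 1] + dr + 1L, pos[, 2] + dc + 1L)]
    }
  }
  structure(list(patches = P, positions = pos, patch_size = patch_size,
                 overlap = overlap, stride = stride, image_dim = dim(image)),
            class = "patch_grid")
}

#' Reassemble an image from overlapping patches
#'
#' Inverse of [extract_patches()]: every output pixel is the arithmetic mean
#' of all patch values covering it. With patches coming straight from
#' `extract_patches` the round trip reproduces the image exactly.
#'
#' @param grid a `patch_grid` (possibly with modified patch values).
#' @param out_height,out_width output dimensions; default the grid's source
#'   image dimensions.
#' @return image plane of the requested dimensions.
#' @export
assemble_patches <- function(grid, out_height = grid$image_dim[1],
                             out_width = grid$image_dim[2]) {
  if (!inherits(grid, "patch_grid")) stopf("grid must be a patch_grid")
  p <- grid$patch_size
  pos <- grid$positions
  if (any(pos[, 1] + p > out_height) || any(pos[, 2] + p > out_width))
    stopf("grid anchors do not fit inside a %dx%d image", out_height, out_width)
  acc <- matrix(0, out_height, out_width)
  cnt <- matrix(0, out_height, out_width)
  for (dr in 0:(p - 1L)) {
    for (dc in 0:(p - 1L)) {
      idx <- cbind(pos[, 1] + dr + 1L, pos[, 2] + dc + 1L)
      vals <- grid$patches[dr * p + dc + 1L, ]
      # anchors are unique, so within one (dr, dc) offset each output pixel
      # is touched at most once and matrix-index assignment accumulates safely
      acc[idx] <- acc[idx] + vals
      cnt[idx] <- cnt[idx] + 1
    }
  }
  if (any(cnt == 0))
    stopf("internal consistency error: %d output pixels uncovered",
          sum(cnt == 0))
  acc / cnt
}
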