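# Bicubic resampling with the Keys kernel (a = -0.5), the convention used
# throughout the single-image super-resolution literature. Resampling is
# separable: a 1-D weight matrix is built per axis and applied by matrix
# multiplication. Output pixel centers are aligned to input pixel centers
# ((i + 0.5) * n_in / n_out - 0.5 in 0-based input coordinates) and
# out-of-range taps are clamped to the border (replicate padding). The
# kernel is never dilated: the Keys kernel sampled at unit spacing
# reproduces constant and linear intensity profiles exactly, which is the
# contract the degradation model is tested against.

keys_cubic <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Dense (n_out x n_in) interpolation weight matrix for one axis.
resample_weights <- function(n_in, n_out) {
  ratio <- n_in / n_out
  u <- (seq_len(n_out) - 0.5) * ratio - 0.5      # 0-based input coords
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    taps <- floor(u[i]) + (-1:2)
    w <- keys_cubic(u[i] - taps)
    w <- w / sum(w)
    taps <- pmin(pmax(taps, 0), n_in - 1)        # replicate border
    for (k in seq_along(taps)) W[i, taps[k] + 1] <- W[i, taps[k] + 1] + w[k]
  }
  W
}

# Core separable resampler; no clipping (callers decide).
resample_bicubic <- function(img, out_h, out_w) {
  Wr <- resample_weights(nrow(img), out_h)
  Wc <- resample_weights(ncol(img), out_w)
  Wr %*% img %*% t(Wc)
}

#' Bicubic degradation model
#'
#' Simulates low-resolution acquisition: bicubic downsampling of a
#' high-resolution image by an integer factor, the standard degradation
#' operator for dictionary-based super-resolution experiments. Images whose
#' dimensions are not divisible by `scale` are cropped (top-left anchored)
#' first; a message reports the crop.
#'
#' @param hr high-resolution image plane in \[0, 1\].
#' @param scale integer downsampling factor, at least 2.
#' @return image plane of dimensions `dim(hr) / scale`, clipped to \[0, 1\].
#' @seealso [upscale_bicubic()], [backproject()]
#' @export
degrade <- function(hr, scale) {
  hr <- as_image_plane(hr)
  scale <- as.integer(scale)
  if (scale < 2) stopf("scale must be an integer >= 2 (got %d)", scale)
  h <- nrow(hr) %/% scale * scale
  w <- ncol(hr) %/% scale * scale
  if (h < scale || w < scale) stopf("image too small to degrade by %d", scale)
  if (h != nrow(hr) || w != ncol(hr)) {
    message(sprintf("degrade: cropping %dx%d to %dx%d (divisible by %d)",
                    nrow(hr), ncol(hr), h, w, scale))
    hr <- hr[seq_len(h), seq_len(w), drop = FALSE]
  }
  clip01(resample_bicubic(hr, h %/% scale, w %/% scale))
}

#' Bicubic upscaling
#'
#' Bicubic interpolation onto a grid `scale` times finer; used both as the
#' comparison baseline and to form the "mid" image (the low-resolution input
#' interpolated to the high-resolution pixel grid) on which gradient
#' features and patch means are computed.
#'
#' @param lr low-resolution image plane.
#' @param scale integer upscaling factor, at least 2.
#' @return image plane of dimensions `dim(lr) * scale`, clipped to \[0, 1\].
#' @export
upscale_bicubic <- function(lr, scale) {
  lr <- as_image_plane(lr)
  scale <- as.integer(scale)
  if (scale < 2) stopf("scale must be an integer >= 2 (got %d)", scale)
  clip01(resample_bicubic(lr, nrow(lr) * scale, ncol(lr) * scale))
}
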