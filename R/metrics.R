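#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical images (zero
#' MSE) return the documented 100 dB sentinel rather than infinity.
#'
#' @param ref,test image planes of identical dimensions.
#' @param data_range dynamic range of the data (1 for \[0, 1\] images; use
#'   255 when reporting on the 8-bit scale).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = 1) {
  if (!all(dim(ref) == dim(test)))
    stopf("psnr: dimension mismatch (%dx%d vs %dx%d)",
          nrow(ref), ncol(ref), nrow(test), ncol(test))
  mse <- mean((ref - test)^2)
  if (mse == 0) return(100)
  min(10 * log10(data_range^2 / mse), 100)
}

# Separable Gaussian filtering, valid mode (output shrinks by the window).
gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

filter_valid <- function(img, g) {
  k <- length(g)
  h <- nrow(img) - k + 1L; w <- ncol(img) - k + 1L
  # rows
  out <- matrix(0, h, ncol(img))
  for (i in seq_len(k)) out <- out + g[i] * img[i:(i + h - 1L), , drop = FALSE]
  # cols
  res <- matrix(0, h, w)
  for (j in seq_len(k)) res <- res + g[j] * out[, j:(j + w - 1L), drop = FALSE]
  res
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard parameters: 11x11 Gaussian window with
#' sigma 1.5, `K1 = 0.01`, `K2 = 0.03`, computed in valid mode (windows
#' fully inside the image).
#'
#' @param ref,test image planes of identical dimensions, at least the
#'   window size in each dimension.
#' @param data_range dynamic range (default 1).
#' @param window_size,sigma Gaussian window controls.
#' @return mean SSIM in \[-1, 1\]; exactly 1 for identical images.
#' @export
ssim <- function(ref, test, data_range = 1, window_size = 11L, sigma = 1.5) {
  if (!all(dim(ref) == dim(test)))
    stopf("ssim: dimension mismatch")
  if (any(dim(ref) < window_size))
    stopf("ssim: image (%dx%d) smaller than the %dx%d window",
          nrow(ref), ncol(ref), window_size, window_size)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  g <- gaussian_window(window_size, sigma)
  mu_x <- filter_valid(ref, g)
  mu_y <- filter_valid(test, g)
  sxx <- filter_valid(ref * ref, g) - mu_x^2
  syy <- filter_valid(test * test, g) - mu_y^2
  sxy <- filter_valid(ref * test, g) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Evaluate a reconstruction against its reference
#'
#' @param ref reference HR image.
#' @param test reconstruction (or an `sr_result`).
#' @param data_range dynamic range for both metrics.
#' @return data frame with one row: `psnr`, `ssim`.
#' @export
evaluate_pair <- function(ref, test, data_range = 1) {
  if (inherits(test, "sr_result")) test <- test$image
  data.frame(psnr = psnr(ref, test, data_range),
             ssim = ssim(ref, test, data_range))
}
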