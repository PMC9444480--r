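#' Super-resolution reconstruction configuration
#'
#' Defaults follow the method's tuned regime: patch 5x5 with overlap 4 at
#' x2 and patch 10x10 with overlap 9 at x4, penalty `lambda = 0.1`, and the
#' global reconstruction constraint enforced by iterative back-projection.
#'
#' @param scale integer super-resolution factor.
#' @param patch_size,overlap patch geometry (defaults per scale).
#' @param lambda sparse-coding penalty.
#' @param backprojection logical; apply [backproject()] after assembly.
#' @param bp_iter,bp_step back-projection iterations and initial step.
#' @return object of class `sr_config`.
#' @export
sr_config <- function(scale = 2L, patch_size = NULL, overlap = NULL,
                      lambda = 0.1, backprojection = TRUE, bp_iter = 20L,
                      bp_step = 1.0) {
  scale <- as.integer(scale)
  if (scale < 2) stopf("scale must be >= 2")
  if (is.null(patch_size) || is.na(patch_size))
    patch_size <- if (scale >= 4) 10L else 5L
  if (is.null(overlap) || is.na(overlap)) overlap <- patch_size - 1L
  structure(list(scale = scale, patch_size = as.integer(patch_size),
                 overlap = as.integer(overlap), lambda = lambda,
                 backprojection = isTRUE(backprojection),
                 bp_iter = as.integer(bp_iter), bp_step = bp_step),
            class = "sr_config")
}

pad_replicate <- function(img, h, w) {
  img[pmin(seq_len(h), nrow(img)), pmin(seq_len(w), ncol(img)), drop = FALSE]
}

#' Iterative back-projection (global reconstruction constraint)
#'
#' Enforces consistency of the estimate with the observed low-resolution
#' image under the bicubic degradation model: the LR residual is upscaled
#' and added back, with the step halved whenever it would increase the
#' LR-consistency residual, so the residual norm is non-increasing over
#' accepted iterations. `bp_iter = 0` is the identity.
#'
#' @param est current HR estimate (`scale` times the LR dimensions).
#' @param lr observed LR image.
#' @param scale integer factor.
#' @param bp_iter maximum iterations.
#' @param bp_step initial step size.
#' @return the corrected image, with attribute `"residual_trace"` (the
#'   LR-consistency residual norm after each accepted iteration, starting
#'   with the input's).
#' @export
backproject <- function(est, lr, scale, bp_iter = 20L, bp_step = 1.0) {
  est <- as_image_plane(est); lr <- as_image_plane(lr)
  if (!all(dim(est) == dim(lr) * scale))
    stopf("est dims (%dx%d) must equal scale x lr dims (%dx%d)",
          nrow(est), ncol(est), nrow(lr) * scale, ncol(lr) * scale)
  r <- lr - clip01(resample_bicubic(est, nrow(lr), ncol(lr)))
  res <- sqrt(sum(r^2))
  trace <- res
  step <- bp_step
  for (it in seq_len(bp_iter)) {
    improved <- FALSE
    while (step > 1e-6) {
      cand <- clip01(est + step * resample_bicubic(r, nrow(est), ncol(est)))
      r_cand <- lr - clip01(resample_bicubic(cand, nrow(lr), ncol(lr)))
      res_cand <- sqrt(sum(r_cand^2))
      if (res_cand <= res) {
        est <- cand; r <- r_cand; res <- res_cand
        trace <- c(trace, res)
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved || res == 0) break
  }
  attr(est, "residual_trace") <- trace
  est
}

#' Patch-based super-resolution reconstruction
#'
#' The full pipeline: (1) bicubic-upscale the LR input to the mid image;
#' (2) compute the four gradient feature planes and extract the overlapping
#' patch grid; (3) sparse-code each feature vector against the LR
#' dictionary; (4) form each HR patch as `D_h alpha` plus the mid-image
#' patch mean (the dictionaries encode detail, not DC); (5) overlap-average
#' the patches back into an image; (6) optionally apply the global
#' reconstruction constraint via [backproject()]. A constant LR image (all
#' features zero, all codes zero) reproduces the bicubic upscale exactly
#' when back-projection is off.
#'
#' @param lr low-resolution image plane.
#' @param cd an `sr_dict` whose geometry matches `config`.
#' @param config an [sr_config()]; defaults are taken from the dictionary's
#'   stored geometry.
#' @param op the [feature_operator()] used at training time.
#' @return object of class `sr_result`: `image` (HR image plane), `config`,
#'   `sparsity` (mean nonzeros per patch code), and `bp_residual_trace`.
#' @export
sr_reconstruct <- function(lr, cd, config = NULL, op = feature_operator()) {
  stopifnot(inherits(cd, "sr_dict"))
  lr <- as_image_plane(lr)
  if (is.null(config))
    config <- sr_config(scale = if (is.na(cd$scale)) 2L else cd$scale,
                        patch_size = if (is.na(cd$patch_size)) NULL
                                     else cd$patch_size,
                        overlap = if (is.na(cd$overlap)) NULL else cd$overlap,
                        lambda = if (is.na(cd$lambda)) 0.1 else cd$lambda)
  p <- config$patch_size
  if (cd$hr_dim != p^2 || cd$lr_dim != 4 * p^2)
    stopf(paste("dictionary geometry (HR dim %d, LR dim %d) does not match",
                "patch size %d (expected HR %d, LR %d)"),
          cd$hr_dim, cd$lr_dim, p, p^2, 4 * p^2)
  mid <- upscale_bicubic(lr, config$scale)
  out_dim <- dim(mid)
  # pad by replication when the upscaled image cannot host a full patch
  padded <- any(out_dim < p)
  if (padded) mid <- pad_replicate(mid, max(nrow(mid), p), max(ncol(mid), p))

  grid <- extract_patches(mid, p, config$overlap)
  feats <- lr_features(mid, op)
  Y <- do.call(rbind, lapply(feats, gather_patches,
                             anchors = grid$positions, p = p))
  codes <- code_matrix(cd$lr, Y, config$lambda, warn = FALSE)
  means <- colMeans(grid$patches)
  grid$patches <- cd$hr$atoms %*% codes + rep(1, p^2) %o% means
  est <- clip01(assemble_patches(grid))
  if (padded) est <- est[seq_len(out_dim[1]), seq_len(out_dim[2]), drop = FALSE]

  bp_trace <- NULL
  if (config$backprojection && config$bp_iter > 0 &&
      all(out_dim == dim(lr) * config$scale)) {
    est <- backproject(est, lr, config$scale, config$bp_iter, config$bp_step)
    bp_trace <- attr(est, "residual_trace")
    attr(est, "residual_trace") <- NULL
  }
  structure(list(image = est, config = config,
                 sparsity = mean(colSums(codes != 0)),
                 bp_residual_trace = bp_trace,
                 provenance = cd$provenance),
            class = "sr_result")
}

#' @export
print.sr_result <- function(x, ...) {
  cat(sprintf("<sr_result> %dx%d reconstruction (x%d, patch %d, overlap %d, lambda %g)\n",
              nrow(x$image), ncol(x$image), x$config$scale,
              x$config$patch_size, x$config$overlap, x$config$lambda))
  cat(sprintf("  dictionary: %s;  mean code sparsity: %.2f;  backprojection: %s\n",
              x$provenance, x$sparsity,
              if (is.null(x$bp_residual_trace)) "off"
              else sprintf("%d accepted steps", length(x$bp_residual_trace) - 1)))
  invisible(x)
}

#' Super-resolve a low-resolution image with a fitted coupled dictionary
#'
#' @param object an `sr_dict` fit.
#' @param newdata LR image plane (matrix in \[0, 1\]).
#' @param config optional [sr_config()] override.
#' @param ... passed to [sr_reconstruct()].
#' @return an `sr_result`; its `image` component is the HR reconstruction.
#' @export
predict.sr_dict <- function(object, newdata, config = NULL, ...) {
  sr_reconstruct(newdata, object, config = config, ...)
}
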