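#' Parameter sweep specification
#'
#' Mirrors the experimental design used to tune the method: one axis
#' (patch size, overlap, or sample budget) is varied while everything else
#' is held fixed, and each setting is scored by PSNR/SSIM of the
#' reconstructions of a set of test images.
#'
#' @param axis `"patch_size"`, `"overlap"`, or `"n_samples"`.
#' @param values vector of axis values (non-empty).
#' @param scale super-resolution factor.
#' @param K,lambda,n_samples,patch_size,overlap fixed configuration (the
#'   swept one is ignored); `overlap = NA` means `patch_size - 1`.
#' @param method `"cascade"` or `"loss_optimized"`.
#' @param cascade_iter,outer_iter,gamma training controls.
#' @param backprojection apply the reconstruction constraint when scoring.
#' @param seed master seed.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(axis = c("patch_size", "overlap", "n_samples"),
                       values, scale = 2L, K = 64L, lambda = 0.1,
                       n_samples = 10000L, patch_size = NULL, overlap = NA,
                       method = "cascade", cascade_iter = 15L,
                       outer_iter = 5L, gamma = 0.7, backprojection = TRUE,
                       seed = 1L) {
  axis <- match.arg(axis)
  if (length(values) < 1) stopf("values must be non-empty")
  if (axis == "overlap" && is.null(patch_size))
    patch_size <- if (scale >= 4) 10L else 5L
  structure(list(axis = axis, values = values, scale = as.integer(scale),
                 K = as.integer(K), lambda = lambda,
                 n_samples = as.integer(n_samples), patch_size = patch_size,
                 overlap = overlap, method = method,
                 cascade_iter = as.integer(cascade_iter),
                 outer_iter = as.integer(outer_iter), gamma = gamma,
                 backprojection = backprojection, seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For each axis value: sample training pairs from the training images,
#' train a coupled dictionary, reconstruct every test image from its
#' bicubic degradation, and record PSNR/SSIM. A setting whose training
#' fails (e.g. a sample budget too small to survive screening) produces a
#' row of `NA`s with `status = "failed"` — the table's dash convention.
#'
#' @param spec a [sweep_spec()].
#' @param train_images list of HR training image planes.
#' @param test_images list (optionally named) of HR test image planes.
#' @param path optional CSV output path (`NA` cells written as `-`).
#' @return data frame: one row per axis value with per-image `psnr_*` and
#'   `ssim_*` columns and a `status` column.
#' @export
run_sweep <- function(spec, train_images, test_images, path = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (is.matrix(test_images)) test_images <- list(test_images)
  nm <- names(test_images) %||% paste0("img", seq_along(test_images))
  nm[nm == ""] <- paste0("img", which(nm == ""))
  rows <- lapply(spec$values, function(v) {
    cfg <- spec
    cfg[[spec$axis]] <- v
    p <- cfg$patch_size %||% (if (cfg$scale >= 4) 10L else 5L)
    o <- if (is.na(cfg$overlap %||% NA)) p - 1L else cfg$overlap
    res <- tryCatch({
      pairs <- sample_training_pairs(train_images, cfg$scale, p,
                                     cfg$n_samples, seed = cfg$seed)
      if (pairs$n < cfg$K)
        stopf("only %d screened pairs for %d atoms: setting is untrainable",
              pairs$n, cfg$K)
      fit <- sr_train(pairs, method = cfg$method, K = cfg$K,
                      lambda = cfg$lambda, gamma = cfg$gamma,
                      cascade_iter = cfg$cascade_iter,
                      outer_iter = cfg$outer_iter, seed = cfg$seed)
      rcfg <- sr_config(cfg$scale, p, o, cfg$lambda,
                        backprojection = cfg$backprojection)
      m <- vapply(test_images, function(im) {
        im <- as_image_plane(im)
        h <- nrow(im) %/% cfg$scale * cfg$scale
        w <- ncol(im) %/% cfg$scale * cfg$scale
        im <- im[seq_len(h), seq_len(w), drop = FALSE]
        rec <- sr_reconstruct(degrade(im, cfg$scale), fit, rcfg)
        c(psnr(im, rec$image), ssim(im, rec$image))
      }, numeric(2))
      list(vals = as.vector(t(m)), status = "ok")
    }, error = function(e) {
      message(sprintf("sweep: %s = %s failed: %s", spec$axis, v,
                      conditionMessage(e)))
      list(vals = rep(NA_real_, 2 * length(test_images)), status = "failed")
    })
    out <- data.frame(value = v)
    out[paste0("psnr_", nm)] <- res$vals[seq_along(nm)]
    out[paste0("ssim_", nm)] <- res$vals[length(nm) + seq_along(nm)]
    out$status <- res$status
    out
  })
  tab <- do.call(rbind, rows)
  names(tab)[1] <- spec$axis
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE, na = "-")
  tab
}
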