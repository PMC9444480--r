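#' Coupled dictionary (the `sr_dict` class)
#'
#' A coupled dictionary is a pair of dictionaries with a shared atom index:
#' column `k` of the high-resolution part and column `k` of the
#' low-resolution (feature) part form one coupled atom, so a sparse code
#' found against the LR part reconstructs the HR patch through the HR part.
#' This is the object returned by [sr_train()]; it carries the patch
#' geometry and training provenance needed for reconstruction.
#'
#' @param hr_atoms `N x K` matrix (or `dictionary`) of HR patch atoms.
#' @param lr_atoms `M x K` matrix (or `dictionary`) of LR feature atoms.
#' @param scale integer super-resolution factor.
#' @param patch_size,overlap patch geometry the atoms were trained on.
#' @param lambda sparse-coding penalty used in training.
#' @param gamma HR/LR error weight (bilevel training), `NA` otherwise.
#' @param provenance one of `"cascade"`, `"loss_optimized"`, `"synthetic"`.
#' @param seed training seed.
#' @param taps_id identifier of the feature taps.
#' @param trace optional `training_trace` data frame.
#' @return object of classes `sr_dict`.
#' @export
coupled_dictionary <- function(hr_atoms, lr_atoms, scale = NA,
                               patch_size = NA, overlap = NA, lambda = NA,
                               gamma = NA, provenance = "synthetic",
                               seed = NA, taps_id = "grad12", trace = NULL) {
  H <- as_atom_matrix(hr_atoms)
  L <- as_atom_matrix(lr_atoms)
  if (ncol(H) != ncol(L))
    stopf("HR and LR parts must share the atom count (%d vs %d)",
          ncol(H), ncol(L))
  geom <- list(patch_size = patch_size, overlap = overlap)
  structure(list(
    hr = dictionary(H, role = "hr", scale = scale, geometry = geom),
    lr = dictionary(L, role = "lr", scale = scale, geometry = geom),
    K = ncol(H), hr_dim = nrow(H), lr_dim = nrow(L),
    scale = scale, patch_size = patch_size, overlap = overlap,
    lambda = lambda, gamma = gamma, provenance = provenance, seed = seed,
    taps_id = taps_id, trace = trace), class = "sr_dict")
}

#' @export
print.sr_dict <- function(x, ...) {
  cat(sprintf("Coupled dictionary (%s)\n", x$provenance))
  cat(sprintf("  atoms: %d   HR dim: %d   LR dim: %d\n",
              x$K, x$hr_dim, x$lr_dim))
  if (!is.na(x$scale))
    cat(sprintf("  scale: x%d   patch: %dx%d   overlap: %d\n", x$scale,
                x$patch_size, x$patch_size, x$overlap))
  if (!is.na(x$lambda)) cat(sprintf("  lambda: %g", x$lambda))
  if (!is.na(x$gamma)) cat(sprintf("   gamma: %g", x$gamma))
  if (!is.na(x$lambda) || !is.na(x$gamma)) cat("\n")
  if (!is.null(x$trace))
    cat(sprintf("  trace: %d recorded iterations (final loss %.6g)\n",
                nrow(x$trace), x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
summary.sr_dict <- function(object, ...) {
  hn <- col_norms(object$hr$atoms)
  ln <- col_norms(object$lr$atoms)
  out <- list(K = object$K, hr_dim = object$hr_dim, lr_dim = object$lr_dim,
              provenance = object$provenance, scale = object$scale,
              hr_norm_range = range(hn), lr_norm_range = range(ln),
              trace = object$trace)
  class(out) <- "summary.sr_dict"
  out
}

#' @export
print.summary.sr_dict <- function(x, ...) {
  cat(sprintf("Coupled dictionary (%s): K = %d, N = %d, M = %d\n",
              x$provenance, x$K, x$hr_dim, x$lr_dim))
  cat(sprintf("  HR atom norms in [%.4f, %.4f]; LR atom norms in [%.4f, %.4f]\n",
              x$hr_norm_range[1], x$hr_norm_range[2],
              x$lr_norm_range[1], x$lr_norm_range[2]))
  if (!is.null(x$trace)) {
    tr <- x$trace
    cat(sprintf("  training: %d iterations, loss %.6g -> %.6g\n",
                nrow(tr), tr$loss[1], tr$loss[nrow(tr)]))
  }
  invisible(x)
}

#' Extract dictionary atoms from a fit
#'
#' @param object an `sr_dict`.
#' @param part `"hr"`, `"lr"`, or `"both"` (a list).
#' @param ... unused.
#' @return atom matrix (or list of the two).
#' @export
coef.sr_dict <- function(object, part = c("both", "hr", "lr"), ...) {
  part <- match.arg(part)
  switch(part, hr = object$hr$atoms, lr = object$lr$atoms,
         both = list(hr = object$hr$atoms, lr = object$lr$atoms))
}

#' Plot a coupled dictionary
#'
#' `type = "atoms"` draws a mosaic of HR atoms reshaped to patches (requires
#' square patch geometry); `type = "trace"` plots the training loss trace.
#'
#' @param x an `sr_dict`.
#' @param type `"atoms"` or `"trace"`.
#' @param max_atoms number of atoms in the mosaic.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.sr_dict <- function(x, type = c("atoms", "trace"), max_atoms = 64, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(x$trace)) stopf("this fit carries no training trace")
    tr <- x$trace
    graphics::plot(tr$iteration, tr$loss, type = "b", xlab = "iteration",
                   ylab = "loss", main = sprintf("%s training", x$provenance),
                   ...)
    return(invisible(x))
  }
  p <- if (!is.na(x$patch_size)) x$patch_size else round(sqrt(x$hr_dim))
  if (p^2 != x$hr_dim) stopf("HR atoms are not square patches; cannot tile")
  k <- min(max_atoms, x$K)
  side <- ceiling(sqrt(k))
  mosaic <- matrix(0.5, side * (p + 1) + 1, side * (p + 1) + 1)
  for (j in seq_len(k)) {
    a <- matrix(x$hr$atoms[, j], p, p, byrow = TRUE)
    rg <- range(a)
    a <- if (rg[2] > rg[1]) (a - rg[1]) / (rg[2] - rg[1]) else a * 0 + 0.5
    r0 <- ((j - 1) %/% side) * (p + 1) + 1
    c0 <- ((j - 1) %% side) * (p + 1) + 1
    mosaic[r0 + seq_len(p), c0 + seq_len(p)] <- a
  }
  graphics::image(t(mosaic)[, nrow(mosaic):1], col = grDevices::gray.colors(256),
                  axes = FALSE, main = sprintf("HR atoms (%s)", x$provenance),
                  ...)
  invisible(x)
}
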