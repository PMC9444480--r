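#' Train a single overcomplete dictionary
#'
#' Classical alternating dictionary learning on one sample matrix: batch
#' L1 sparse coding against the current dictionary, then a dictionary update
#' minimizing the Frobenius fit `||X - D A||_F^2` subject to unit-ball
#' column norms (closed-form regularized least squares followed by scaling
#' any over-norm column back onto the unit sphere). An update is accepted
#' only when it does not increase the fit, so the recorded objective is
#' non-increasing across alternations. Atoms unused in a sweep ("dead"
#' atoms) and the lesser-used atom of any near-duplicate pair are re-seeded
#' from the worst-represented samples; a re-seed that would raise the next
#' iteration's objective is rolled back.
#'
#' @param X `n x n_samples` sample matrix.
#' @param K number of atoms (>= 2); the method's full-size default is 512.
#' @param lambda L1 penalty weight of the coding step.
#' @param n_iter number of alternations.
#' @param seed seed for the initialization (atoms start from random samples).
#' @param tol,max_iter sparse-coder controls (see [solver_config()]).
#' @return a [dictionary()] with attribute `"trace"`: a data frame with
#'   per-iteration objective (mean per-sample lasso objective), fit term,
#'   and mean code sparsity.
#' @export
train_dictionary <- function(X, K, lambda, n_iter = 30L, seed = 1L,
                             tol = 1e-6, max_iter = 1000L) {
  if (!is.matrix(X) || ncol(X) < 1) stopf("X must be a non-empty matrix")
  K <- as.integer(K)
  if (K < 2) stopf("K must be >= 2")
  n <- ncol(X)
  if (n < K)
    warnf("only %d samples for %d atoms; recovery may be unreliable", n, K)

  D <- with_seed(seed, {
    init_idx <- sample.int(n, min(K, n))
    D0 <- X[, init_idx, drop = FALSE]
    if (K > n)
      D0 <- cbind(D0, matrix(rnorm(nrow(X) * (K - n)), nrow(X)))
    D0
  })
  # constant samples can yield zero columns; replace with random directions
  zero <- col_norms(D) == 0
  if (any(zero))
    D[, zero] <- with_seed(seed + 1L, matrix(rnorm(nrow(X) * sum(zero)),
                                             nrow(X)))
  D <- normalize_columns(D)

  trace <- data.frame(iteration = integer(), objective = numeric(),
                      fit = numeric(), sparsity = numeric())
  last_obj <- Inf
  D_saved <- D
  recycled <- FALSE
  for (it in seq_len(n_iter)) {
    A <- code_matrix(D, X, lambda, tol, max_iter, warn = FALSE)
    fit <- mean(colSums((X - D %*% A)^2))
    obj <- fit + lambda * mean(colSums(abs(A)))
    if (recycled && obj > last_obj + 1e-12) {
      # atom recycling hurt: fall back to the saved dictionary, whose coding
      # objective cannot exceed the previous iteration's
      D <- D_saved
      A <- code_matrix(D, X, lambda, tol, max_iter, warn = FALSE)
      fit <- mean(colSums((X - D %*% A)^2))
      obj <- fit + lambda * mean(colSums(abs(A)))
    }
    trace <- rbind(trace, data.frame(iteration = it, objective = obj,
                                     fit = fit,
                                     sparsity = mean(colSums(A != 0))))
    last_obj <- obj

    # MOD-style update with unit-ball clipping, accepted only on non-increase
    G <- A %*% t(A)
    diag(G) <- diag(G) + 1e-8
    D_new <- clip_columns_to_unit_ball(t(solve(G, A %*% t(X))))
    fit_new <- mean(colSums((X - D_new %*% A)^2))
    if (fit_new <= fit + 1e-12) D <- D_new

    D_saved <- D
    recycled <- FALSE
    # re-seed dead atoms (unused in this sweep) and the lesser-used atom of
    # any near-duplicate pair from the worst-represented samples
    usage <- rowSums(A != 0)
    stale <- usage == 0
    if (it < n_iter) {
      Dn <- normalize_columns(D)
      coh <- abs(crossprod(Dn))
      coh[upper.tri(coh, diag = TRUE)] <- 0
      dup <- which(coh > 0.98, arr.ind = TRUE)
      for (r in seq_len(nrow(dup))) {
        pair <- dup[r, ]
        stale[pair[which.min(usage[pair])]] <- TRUE
      }
    }
    if (any(stale)) {
      resid_norm <- colSums((X - D %*% A)^2)
      worst <- order(resid_norm, decreasing = TRUE)
      idx <- which(stale)
      for (j in seq_along(idx)) {
        src <- X[, worst[(j - 1L) %% length(worst) + 1L]]
        if (sum(src^2) > 0) {
          D[, idx[j]] <- src / sqrt(sum(src^2))
          recycled <- TRUE
        }
      }
    }
  }
  out <- dictionary(D, role = "single")
  attr(out, "trace") <- trace
  out
}
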