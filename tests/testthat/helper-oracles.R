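# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own computational paths: brute-force
# summation, exhaustive enumeration, and closed-form solves only.

# Exhaustive-support lasso oracle: minimize ||x - D a||^2 + lambda ||a||_1
# by enumerating every support/sign pattern, solving each pattern's
# stationarity system in closed form, and keeping the best sign-consistent
# candidate (a = 0 is always a candidate). Valid for small K only.
oracle_lasso_objective <- function(D, x, lambda) {
  K <- ncol(D)
  best <- sum(x^2)                     # a = 0
  # enumerate sign vectors in {-1, 0, 1}^K
  for (code in seq_len(3^K) - 1L) {
    s <- integer(K)
    c0 <- code
    for (k in seq_len(K)) { s[k] <- c0 %% 3L - 1L; c0 <- c0 %/% 3L }
    sup <- which(s != 0L)
    if (length(sup) == 0) next
    Ds <- D[, sup, drop = FALSE]
    G <- crossprod(Ds)
    if (rcond(G) < 1e-12) next
    a <- solve(G, crossprod(Ds, x) - (lambda / 2) * s[sup])
    if (any(sign(a) != s[sup])) next   # sign-inconsistent pattern
    obj <- sum((x - Ds %*% a)^2) + lambda * sum(abs(a))
    if (obj < best) best <- obj
  }
  best
}

# Brute-force correlation: per-pixel sliding window with replicate padding.
oracle_correlate <- function(img, f) {
  fr <- nrow(f); fc <- ncol(f)
  cr <- (fr - 1L) %/% 2L; cc <- (fc - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0
    for (i in seq_len(fr)) for (j in seq_len(fc)) {
      rr <- min(max(r + i - 1L - cr, 1L), h)
      cc2 <- min(max(c + j - 1L - cc, 1L), w)
      acc <- acc + f[i, j] * img[rr, cc2]
    }
    out[r, c] <- acc
  }
  out
}

# Direct per-window SSIM (Gaussian weights, valid mode), no filtering code
# shared with the implementation.
oracle_ssim <- function(x, y, data_range = 1, size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  h <- nrow(x) - size + 1L; w <- ncol(x) - size + 1L
  vals <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    wx <- x[r:(r + size - 1L), c:(c + size - 1L)]
    wy <- y[r:(r + size - 1L), c:(c + size - 1L)]
    mx <- sum(W * wx); my <- sum(W * wy)
    vx <- sum(W * wx^2) - mx^2; vy <- sum(W * wy^2) - my^2
    vxy <- sum(W * wx * wy) - mx * my
    vals[r, c] <- ((2 * mx * my + C1) * (2 * vxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  mean(vals)
}

# Joint loss with every sample's active set and signs held fixed: codes are
# re-solved from the fixed-support stationarity system at the (possibly
# perturbed) LR dictionary. This is the function whose finite differences
# the implicit gradient must match.
oracle_joint_loss_fixed_support <- function(Dh, Dl, X, Y, supports, signs,
                                            gamma, lambda) {
  n <- ncol(X)
  L <- 0
  for (i in seq_len(n)) {
    sup <- supports[[i]]
    if (length(sup) == 0) {
      rx <- sum(X[, i]^2); ry <- sum(Y[, i]^2)
    } else {
      Dt <- Dl[, sup, drop = FALSE]
      ct <- solve(crossprod(Dt),
                  crossprod(Dt, Y[, i]) - (lambda / 2) * signs[[i]])
      rx <- sum((Dh[, sup, drop = FALSE] %*% ct - X[, i])^2)
      ry <- sum((Dt %*% ct - Y[, i])^2)
    }
    L <- L + 0.5 * (gamma * rx + (1 - gamma) * ry)
  }
  L / n
}

# Central finite differences of the fixed-support joint loss in D_l.
oracle_fd_gradient <- function(Dh, Dl, X, Y, supports, signs, gamma, lambda,
                               h = 1e-5) {
  G <- matrix(0, nrow(Dl), ncol(Dl))
  for (m in seq_len(nrow(Dl))) for (k in seq_len(ncol(Dl))) {
    Dp <- Dl; Dp[m, k] <- Dp[m, k] + h
    Dm <- Dl; Dm[m, k] <- Dm[m, k] - h
    G[m, k] <- (oracle_joint_loss_fixed_support(Dh, Dp, X, Y, supports,
                                                signs, gamma, lambda) -
                oracle_joint_loss_fixed_support(Dh, Dm, X, Y, supports,
                                                signs, gamma, lambda)) /
      (2 * h)
  }
  G
}

# Random unit-norm atom matrix.
rand_dict <- function(n, K, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * K), n)
  sweep(A, 2, sqrt(colSums(A^2)), "/")
}

# Tiny deterministic training-pairs fixture drawn from a known coupled
# dictionary.
make_generative_fixture <- function(N = 16, M = 24, K = 20, s = 2,
                                    sigma = 0.01, n = 400, seed = 5) {
  spec <- generative_spec(hr_dim = N, lr_dim = M, K = K, sparsity = s,
                          noise = sigma, n_samples = n, seed = seed)
  cd <- make_coupled_dictionary(spec)
  list(cd = cd, pairs = sample_generative_pairs(cd, spec), spec = spec)
}

# Small local matrix helpers (kept independent of package internals).
col_norms_for_test <- function(M) sqrt(colSums(M^2))
normalize_cols_for_test <- function(M) sweep(M, 2, pmax(col_norms_for_test(M), 1e-300), "/")

tempfile_with <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}
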