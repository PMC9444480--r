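# Implicit-differentiation gradient of the joint loss in the LR dictionary,
# checked against central finite differences of the fixed-active-set loss.

grad_instance <- function(M, K, N, n, gamma, lambda, seed) {
  set.seed(seed)
  Dh <- rand_dict(N, K, seed + 1)
  Dl <- rand_dict(M, K, seed + 2)
  cd <- coupled_dictionary(Dh, Dl)
  X <- matrix(rnorm(N * n), N)
  Y <- matrix(rnorm(M * n), M)
  codes <- dictSR:::code_matrix(Dl, Y, lambda, tol = 1e-12, max_iter = 20000)
  keep <- vapply(seq_len(n), function(i) {
    sup <- which(codes[, i] != 0)
    length(sup) == 0 ||
      rcond(crossprod(Dl[, sup, drop = FALSE])) >= 1e-8
  }, logical(1))
  X <- X[, keep, drop = FALSE]; Y <- Y[, keep, drop = FALSE]
  codes <- codes[, keep, drop = FALSE]
  n <- ncol(X)
  pairs <- training_pairs(X, Y)
  supports <- lapply(seq_len(n), function(i) which(codes[, i] != 0))
  signs <- lapply(seq_len(n), function(i) sign(codes[supports[[i]], i]))
  list(cd = cd, pairs = pairs, codes = codes, supports = supports,
       signs = signs, Dh = Dh, Dl = Dl, X = X, Y = Y,
       gamma = gamma, lambda = lambda)
}

expect_grad_matches_fd <- function(inst, tol = 1e-3) {
  G <- grad_lr_dictionary(inst$cd, inst$pairs, inst$gamma, inst$lambda,
                          codes = inst$codes)
  Gfd <- oracle_fd_gradient(inst$Dh, inst$Dl, inst$X, inst$Y, inst$supports,
                            inst$signs, inst$gamma, inst$lambda)
  active_cols <- sort(unique(unlist(inst$supports)))
  a <- G[, active_cols]; b <- Gfd[, active_cols]
  rel <- abs(a - b) / pmax(abs(b), 1e-6)
  expect_lt(max(rel), tol)
  invisible(max(rel))
}

test_that("the implicit gradient vanishes in the two degenerate regimes", {
  set.seed(43)
  Dh <- rand_dict(6, 8, 101); Dl <- rand_dict(7, 8, 102)
  cd <- coupled_dictionary(Dh, Dl)
  X <- matrix(rnorm(6 * 4), 6); Y <- matrix(rnorm(7 * 4), 7)
  pairs <- training_pairs(X, Y)

  # penalty large enough that every code is zero: both terms vanish
  lam_big <- 2 * max(abs(crossprod(Dl, Y))) + 1
  G <- grad_lr_dictionary(cd, pairs, gamma = 0.7, lambda = lam_big)
  expect_equal(G, matrix(0, 7, 8), ignore_attr = TRUE)

  # gamma = 1 with a perfectly fitting HR dictionary: upper-level gradient
  # in the code vanishes, so chain and direct terms are both zero
  codes <- dictSR:::code_matrix(Dl, Y, 0.05, tol = 1e-12, max_iter = 20000)
  pairs2 <- training_pairs(Dh %*% codes, Y)
  G2 <- grad_lr_dictionary(cd, pairs2, gamma = 1, lambda = 0.05,
                           codes = codes)
  expect_lt(max(abs(G2)), 1e-9)
})

test_that("implicit gradient matches finite differences on the spec instance", {
  inst <- grad_instance(M = 6, K = 8, N = 8, n = 5, gamma = 0.7,
                        lambda = 0.05, seed = 47)
  expect_grad_matches_fd(inst)
})

test_that("implicit gradient matches finite differences across regimes", {
  cfgs <- expand.grid(gamma = c(0.3, 1.0), lambda = c(0.05, 0.2))
  for (i in seq_len(nrow(cfgs))) {
    inst <- grad_instance(M = sample(5:8, 1), K = sample(6:10, 1),
                          N = sample(5:8, 1), n = sample(3:6, 1),
                          gamma = cfgs$gamma[i], lambda = cfgs$lambda[i],
                          seed = 200 + i)
    expect_grad_matches_fd(inst)
  }
})

test_that("the gradient errors out only when every sample is degenerate", {
  # duplicated atoms make the active Gram singular whenever both copies of
  # an atom activate together; engineer exact duplicates and identical data
  Dl <- cbind(c(1, 0), c(1, 0), c(0, 1))
  Dh <- rand_dict(3, 3, 103)
  cd <- coupled_dictionary(Dh, Dl)
  Y <- matrix(c(2, 0), 2, 1)
  X <- matrix(rnorm(3), 3, 1)
  pairs <- training_pairs(X, Y)
  codes <- matrix(c(0.5, 0.5, 0), 3, 1)  # both duplicates active
  expect_error(suppressWarnings(
    grad_lr_dictionary(cd, pairs, 0.7, 0.1, codes = codes)), "singular")
})
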