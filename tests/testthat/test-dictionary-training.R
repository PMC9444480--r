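test_that("single-dictionary training recovers generating atoms", {
  # noiseless 1-sparse signed-unit combinations of K known unit atoms,
  # K = n. Alternating minimization has local minima in which one atom
  # settles on a mixture of two generators, so this is a fixed-seed example
  # of a basin that converges to the generator; the method-level recovery
  # property is exercised on coupled data in the acceptance suite.
  set.seed(13)
  n <- 64; K <- 64
  gen <- rand_dict(n, K, seed = 71)
  C <- matrix(0, K, 1500)
  for (j in 1:1500) C[sample(K, 1), j] <- sample(c(-1, 1), 1)
  X <- gen %*% C
  d <- train_dictionary(X, K, lambda = 0.3, n_iter = 20, seed = 15)
  m <- match_atoms(d$atoms, gen)
  expect_true(all(m$cosines >= 0.99))
})

test_that("a repeated sample pins an atom to its direction", {
  x <- c(0.6, 0.8, 0)
  X <- matrix(x, 3, 50)
  suppressWarnings(d <- train_dictionary(X, 2, lambda = 1e-3, n_iter = 10,
                                         seed = 1))
  cosines <- abs(crossprod(normalize_cols_for_test(d$atoms), x / sqrt(sum(x^2))))
  expect_gte(max(cosines), 1 - 1e-6)
  tr <- attr(d, "trace")
  expect_true(all(diff(tr$objective) <= 1e-10))
  expect_lt(tr$fit[nrow(tr)], 1e-6)
})

test_that("training objective is non-increasing and guards reject bad updates", {
  fx <- make_generative_fixture(N = 10, M = 14, K = 12, s = 2, sigma = 0.02,
                                n = 300, seed = 15)
  cas <- build_cascade(fx$pairs)
  d <- train_dictionary(cas$X_c, 12, 0.001, n_iter = 15, seed = 16)
  tr <- attr(d, "trace")
  expect_true(all(diff(tr$objective) <= 1e-10))
  expect_true(all(diff(tr$fit) <= 1e-8))
})

test_that("cascade stacking applies reciprocal-dimension weights", {
  pairs <- training_pairs(matrix(1, 25, 1), matrix(1, 100, 1))
  cas <- build_cascade(pairs)
  expect_equal(cas$X_c[1, 1], 1 / 25)
  expect_equal(cas$X_c[26, 1], 1 / 100)
  expect_equal(cas$recipe$w_h, 0.04)
  expect_equal(cas$recipe$w_l, 0.01)
  # effective penalty of the stacked problem: lambda (1/N + 1/M)
  expect_equal(0.1 * (cas$recipe$w_h + cas$recipe$w_l), 0.005)
  # split/unscale round-trips the stacked matrix
  parts <- dictSR:::split_cascade_dictionary(cas$X_c, cas$recipe)
  s <- max(1, sqrt(sum(rep(1, 25)^2)), sqrt(sum(rep(1, 100)^2)))
  expect_equal(parts$hr * s, matrix(1, 25, 1))
  expect_equal(parts$lr * s, matrix(1, 100, 1))
})

test_that("cascade training drives the objective to the noise floor on
           noiseless generative data", {
  fx <- make_generative_fixture(N = 12, M = 20, K = 16, s = 2, sigma = 0,
                                n = 600, seed = 17)
  fit <- train_cascade(fx$pairs, cascade_config(K = 16, lambda = 0.001,
                                                n_iter = 40, seed = 18))
  expect_s3_class(fit, "sr_dict")
  expect_identical(fit$provenance, "cascade")
  tr <- fit$trace
  expect_true(all(diff(tr$loss) <= 1e-12))
  expect_lt(tr$fit[nrow(tr)], 1e-6)    # per-sample stacked residual
  expect_lte(max(col_norms_for_test(coef(fit, "hr"))), 1 + 1e-9)
  expect_lte(max(col_norms_for_test(coef(fit, "lr"))), 1 + 1e-9)
  expect_error(train_cascade(training_pairs(matrix(0, 2, 0), matrix(0, 3, 0))),
               "empty")
})

test_that("screening keeps exactly the above-threshold columns", {
  set.seed(19)
  # columns with known variances 0, 5e-5, 2e-4, 0.3
  mk <- function(v) {
    z <- rnorm(25); z <- z - mean(z)
    if (var(z) > 0) z <- z * sqrt(v / var(z))
    z + 0.5
  }
  hr <- cbind(rep(0.5, 25), mk(5e-5), mk(2e-4), mk(0.3))
  pairs <- training_pairs(hr, matrix(rnorm(100 * 4), 100))
  kept <- screen_pairs(pairs, 1e-4)
  expect_equal(kept$n, 2)
  # alignment: LR columns follow their HR columns
  expect_equal(kept$lr, pairs$lr[, 3:4])
  # idempotence
  expect_equal(screen_pairs(kept, 1e-4)$hr, kept$hr)
  # threshold 0 keeps everything non-constant
  expect_equal(screen_pairs(pairs, 0)$n, 3)
  expect_error(screen_pairs(training_pairs(matrix(0.2, 9, 5),
                                           matrix(0, 9, 5)), 1e-4),
               "threshold")
})

test_that("pair sampling is seeded and screens flat patches", {
  img <- make_phantom(phantom_spec(64, "mixed", seed = 23))
  p1 <- sample_training_pairs(img, 2, 5, 500, seed = 7)
  p2 <- sample_training_pairs(img, 2, 5, 500, seed = 7)
  p3 <- sample_training_pairs(img, 2, 5, 500, seed = 8)
  expect_identical(p1$hr, p2$hr)
  expect_identical(p1$lr, p2$lr)
  expect_false(identical(p1$hr, p3$hr))
  expect_equal(p1$hr_dim, 25)
  expect_equal(p1$lr_dim, 100)
  # HR columns are mean-removed
  expect_lt(max(abs(colMeans(p1$hr))), 1e-12)
  # constant image: everything is screened out
  expect_error(sample_training_pairs(matrix(0.5, 64, 64), 2, 5, 100,
                                     seed = 1), "screening")
})

test_that("joint loss separates the HR and LR residuals", {
  fx <- make_generative_fixture(N = 8, M = 10, K = 8, s = 1, sigma = 0,
                                n = 40, seed = 29)
  # lambda = 0 on noiseless 1-sparse data: both residuals vanish
  jl <- joint_loss(fx$cd, fx$pairs, gamma = 0.7, lambda = 0)
  expect_lt(jl$R_x, 1e-8)
  expect_lt(jl$R_y, 1e-8)
  expect_lt(jl$L, 1e-8)

  # gamma = 1 carries only the HR term
  set.seed(30)
  cd2 <- coupled_dictionary(rand_dict(8, 8, 91), rand_dict(10, 8, 92))
  jl2 <- joint_loss(cd2, fx$pairs, gamma = 1, lambda = 0.05)
  expect_equal(jl2$L, 0.5 * jl2$R_x)

  # two-sample toy instance against direct arithmetic with fixed codes
  Dh <- matrix(c(1, 0, 0, 1), 2)
  Dl <- matrix(c(0.6, 0.8, -0.8, 0.6), 2)
  cd3 <- coupled_dictionary(Dh, Dl)
  X <- cbind(c(1, 0), c(0, 2)); Y <- cbind(c(0.6, 0.8), c(-1.6, 1.2))
  pr <- training_pairs(X, Y)
  C <- dictSR:::code_matrix(Dl, Y, 0.1)
  rx <- colSums((Dh %*% C - X)^2); ry <- colSums((Dl %*% C - Y)^2)
  jl3 <- joint_loss(cd3, pr, gamma = 0.3, lambda = 0.1)
  expect_equal(jl3$L, mean(0.5 * (0.3 * rx + 0.7 * ry)), tolerance = 1e-12)
})

test_that("HR dictionary update solves the constrained least squares", {
  set.seed(31)
  # identity codes: unconstrained minimizer is X itself (columns inside the
  # unit ball stay exact)
  X <- matrix(rnorm(6 * 5, sd = 0.2), 6)
  X <- sweep(X, 2, pmax(1, col_norms_for_test(X) * 1.01), "/")
  cd <- coupled_dictionary(rand_dict(6, 5, 93), rand_dict(4, 5, 94))
  pr <- training_pairs(X, matrix(rnorm(4 * 5), 4))
  newD <- update_hr_dictionary(cd, pr, lambda = 0.1, codes = diag(5))
  expect_equal(newD$atoms, X, tolerance = 1e-6)

  # random instance with inactive constraints matches dense normal equations
  C <- matrix(rnorm(5 * 40), 5)
  X2 <- 0.1 * matrix(rnorm(6 * 40), 6)
  pr2 <- training_pairs(X2, matrix(rnorm(4 * 40), 4))
  newD2 <- update_hr_dictionary(cd, pr2, lambda = 0.1, codes = C)
  oracle <- X2 %*% t(C) %*% solve(C %*% t(C) + 1e-8 * diag(5))
  expect_equal(newD2$atoms, oracle, tolerance = 1e-8)

  # all-zero codes: unchanged, with a warning
  expect_warning(same <- update_hr_dictionary(cd, pr2, lambda = 0.1,
                                              codes = matrix(0, 5, 40)),
                 "unchanged")
  expect_identical(same$atoms, cd$hr$atoms)
})

test_that("LR dictionary line search only accepts strict descent", {
  fx <- make_generative_fixture(N = 10, M = 12, K = 10, s = 2, sigma = 0.05,
                                n = 150, seed = 33)
  set.seed(34)
  cd <- coupled_dictionary(rand_dict(10, 10, 95), rand_dict(12, 10, 96))
  cfg <- bilevel_config(gamma = 0.7, lambda = 0.05)
  before <- joint_loss(cd, fx$pairs, 0.7, 0.05)
  res <- update_lr_dictionary(cd, fx$pairs, cfg)
  expect_lt(res$loss$L, before$L)
  expect_gt(res$step, 0)
  expect_lte(max(col_norms_for_test(res$lr$atoms)), 1 + 1e-12)

  # zero gradient (all codes empty under a huge penalty): unchanged, step0
  cfg0 <- bilevel_config(gamma = 0.7, lambda = 1e6, step0 = 0.25)
  res0 <- update_lr_dictionary(cd, fx$pairs, cfg0)
  expect_identical(res0$lr$atoms, cd$lr$atoms)
  expect_equal(res0$step, 0.25)
})

test_that("column projection lands over-norm columns exactly on the sphere", {
  M <- cbind(c(3, 4), c(0.3, 0.4))
  P <- dictSR:::clip_columns_to_unit_ball(M)
  expect_equal(sqrt(sum(P[, 1]^2)), 1)
  expect_equal(P[, 2], c(0.3, 0.4))
})

test_that("bilevel training is monotone and exits early at a fixed point", {
  fx <- make_generative_fixture(N = 10, M = 14, K = 12, s = 2, sigma = 0.01,
                                n = 400, seed = 35)
  cas <- train_cascade(fx$pairs, cascade_config(K = 12, lambda = 0.05,
                                                n_iter = 25, seed = 36))
  cfg <- bilevel_config(gamma = 0.7, lambda = 0.05, outer_iter = 8)
  fit <- train_loss_optimized(fx$pairs, cas, cfg)
  expect_identical(fit$provenance, "loss_optimized")
  expect_true(all(diff(fit$trace$loss) <= 1e-12))
  expect_lte(fit$trace$loss[nrow(fit$trace)], fit$trace$loss[1])
  expect_lte(fit$trace$R_x[nrow(fit$trace)], fit$trace$R_x[1] + 1e-12)
  expect_equal(fit$gamma, 0.7)
})

test_that("an already-optimal initialization is a fixed point", {
  # noiseless 1-sparse data coded against the generator itself with no
  # penalty: both residuals are zero, so training exits on the first round
  fx <- make_generative_fixture(N = 10, M = 14, K = 12, s = 1, sigma = 0,
                                n = 200, seed = 37)
  cfg <- bilevel_config(gamma = 0.7, lambda = 0, outer_iter = 10)
  fit <- train_loss_optimized(fx$pairs, fx$cd, cfg)
  expect_lte(nrow(fit$trace), 2)
  expect_lt(fit$trace$loss[nrow(fit$trace)], 1e-10)
  expect_equal(fit$lr$atoms, fx$cd$lr$atoms, tolerance = 1e-8)
})
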