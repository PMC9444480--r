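test_that("lasso objective evaluates the penalized residual exactly", {
  d <- c(1, 0, 0)
  D <- matrix(d, 3, 1)
  x <- c(0.5, 0.2, 0)
  expect_equal(lasso_objective(D, x, 0, 1), sum(x^2))
  expect_equal(lasso_objective(D, d, 1, 0), 0)
  # single unit atom, x = d, alpha = 0.5, lambda = 1: (1-0.5)^2 + 0.5
  expect_equal(lasso_objective(D, d, 0.5, 1), 0.75)
  expect_error(lasso_objective(D, c(1, 2), c(1), 1), "length")
})

test_that("scalar problems reproduce the soft-threshold closed form", {
  d <- c(1, 0)
  D <- matrix(d, 2, 1)
  expect_equal(sparse_code(D, c(0, 0), lambda = 0.3)$coefficients, 0)
  expect_equal(sparse_code(D, d, lambda = 0)$coefficients, 1)
  # minimizer of (1 - a)^2 + |a| is a = 0.5
  expect_equal(sparse_code(D, d, lambda = 1)$coefficients, 0.5)
  sc <- sparse_code(D, d, lambda = 1)
  expect_equal(sc$active_set, 1L)
  expect_true(sc$converged)
})

test_that("solver matches the exhaustive-support oracle on small problems", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:6, 1); K <- sample(4:8, 1)
    D <- rand_dict(n, K, seed = 100 + rep)
    x <- rnorm(n)
    for (lam in c(0, 0.05, 0.5)) {
      sc <- sparse_code(D, x, lambda = lam, tol = 1e-9, max_iter = 5000)
      obj <- lasso_objective(D, x, sc, lam)
      expect_lte(obj, oracle_lasso_objective(D, x, lam) + 1e-8)
      expect_lte(obj, sum(x^2) + 1e-12)   # never worse than alpha = 0
    }
  }
})

test_that("solver agrees with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 30; K <- 12
  D <- rand_dict(n, K, seed = 9)
  x <- rnorm(n)
  lam <- 0.4
  # glmnet minimizes (1/2n)||x - D b||^2 + lambda_g ||b||_1, so
  # lambda_g = lam / (2 n) matches ||x - D b||^2 + lam ||b||_1
  fit <- glmnet::glmnet(D, x, lambda = lam / (2 * n), intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14)
  b <- as.numeric(fit$beta)
  ours <- sparse_code(D, x, lambda = lam, tol = 1e-10, max_iter = 5000)
  expect_equal(lasso_objective(D, x, ours, lam),
               lasso_objective(D, x, b, lam), tolerance = 1e-7)
})

test_that("a large enough penalty forces the zero code", {
  set.seed(4)
  D <- rand_dict(5, 7, seed = 21)
  x <- rnorm(5)
  lam <- 2 * max(abs(crossprod(D, x)))    # stationarity threshold at 0
  expect_equal(sparse_code(D, x, lambda = lam)$coefficients, rep(0, 7))
})

test_that("solution tracks column permutations of the dictionary", {
  set.seed(5)
  D <- rand_dict(6, 8, seed = 31)
  x <- rnorm(6)
  perm <- sample(8)
  a1 <- sparse_code(D, x, lambda = 0.1, tol = 1e-10)$coefficients
  a2 <- sparse_code(D[, perm], x, lambda = 0.1, tol = 1e-10)$coefficients
  expect_equal(a2, a1[perm], tolerance = 1e-8)
})

test_that("internal objective is non-increasing across sweeps", {
  set.seed(6)
  D <- rand_dict(8, 12, seed = 41)
  X <- matrix(rnorm(8 * 4), 8)
  res <- dictSR:::.cd_lasso_cpp(D, X, 0.1, 1e-12, 200L, TRUE)
  for (tr in res$objective_trace)
    expect_true(all(diff(tr) <= 1e-12))
})

test_that("batch coding equals independent single solves, order preserved", {
  set.seed(8)
  D <- rand_dict(4, 6, seed = 51)
  X <- matrix(rnorm(4 * 5), 4)
  batch <- sparse_code_batch(D, X, solver_config(lambda = 0.1))
  expect_length(batch, 5)
  for (j in 1:5)
    expect_identical(batch[[j]]$coefficients,
                     sparse_code(D, X[, j], lambda = 0.1)$coefficients)
  # all-zero signals give all-zero codes
  z <- sparse_code_batch(D, matrix(0, 4, 3), solver_config(lambda = 0.1))
  for (sc in z) expect_equal(sc$coefficients, rep(0, 6))
})

test_that("zero-norm atoms are tolerated and get zero coefficients", {
  D <- cbind(c(1, 0), c(0, 0))
  sc <- sparse_code(D, c(0.8, 0), lambda = 0.1)
  expect_equal(sc$coefficients[2], 0)
  expect_equal(sc$coefficients[1], (0.8 - 0.05), tolerance = 1e-9)
})

test_that("hitting the iteration cap flags the result instead of failing", {
  D <- rand_dict(6, 9, seed = 61)
  x <- rnorm(6)
  expect_warning(sc <- sparse_code(D, x, lambda = 0.01, tol = 1e-14,
                                   max_iter = 2),
                 "did not converge")
  expect_false(sc$converged)
  expect_true(all(is.finite(sc$coefficients)))
})
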