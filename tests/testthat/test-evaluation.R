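test_that("psnr follows its closed form and is symmetric", {
  a <- matrix(0.5, 20, 20)
  expect_equal(psnr(a, a), 100)        # zero-MSE sentinel
  # 8-bit scale: constant offset of 16 at range 255
  ref <- matrix(100, 16, 16); test <- matrix(116, 16, 16)
  expect_equal(psnr(ref, test, data_range = 255),
               10 * log10(255^2 / 256), tolerance = 1e-12)
  expect_equal(10 * log10(255^2 / 256), 24.0475, tolerance = 1e-4)

  set.seed(61)
  x <- matrix(runif(64), 8); y <- matrix(runif(64), 8)
  expect_equal(psnr(x, y), psnr(y, x))
  # direct-sum MSE oracle
  mse <- sum((x - y)^2) / 64
  expect_equal(psnr(x, y), 10 * log10(1 / mse), tolerance = 1e-10)
  expect_error(psnr(x, matrix(0, 4, 4)), "mismatch")
})

test_that("ssim matches a direct per-window computation", {
  set.seed(62)
  x <- matrix(runif(15 * 13), 15, 13)
  y <- pmin(pmax(x + matrix(rnorm(15 * 13, sd = 0.1), 15), 0), 1)
  expect_equal(ssim(x, y), oracle_ssim(x, y), tolerance = 1e-12)
  expect_equal(ssim(x, x), 1)

  # contrast inversion of a high-contrast image scores below 0.5
  img <- make_phantom(phantom_spec(48, "edges", seed = 63,
                                   contrast = c(0, 1)))
  expect_lt(ssim(img, 1 - img), 0.5)

  # constants: only the luminance term differs from 1
  c1 <- matrix(0.3, 12, 12); c2 <- matrix(0.6, 12, 12)
  C1 <- 0.01^2
  expect_equal(ssim(c1, c2),
               (2 * 0.3 * 0.6 + C1) / (0.3^2 + 0.6^2 + C1),
               tolerance = 1e-12)
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("parameter sweeps produce a finite table per axis value", {
  train <- lapply(1:2, function(i)
    make_phantom(phantom_spec(64, "mixed", seed = 70 + i)))
  test <- lapply(1:2, function(i)
    make_phantom(phantom_spec(64, "mixed", seed = 80 + i)))
  spec <- sweep_spec("patch_size", values = c(4, 5), scale = 2, K = 24,
                     n_samples = 1200, cascade_iter = 5, method = "cascade",
                     backprojection = FALSE, seed = 3)
  tab <- run_sweep(spec, train, test)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$status == "ok"))
  expect_true(all(is.finite(as.matrix(tab[, grep("psnr|ssim", names(tab))]))))
  # deterministic under the fixed seed
  tab2 <- run_sweep(spec, train, test)
  expect_identical(tab, tab2)
})

test_that("untrainable sweep settings are rendered as failed rows", {
  train <- list(make_phantom(phantom_spec(64, "mixed", seed = 91)))
  test <- list(make_phantom(phantom_spec(64, "mixed", seed = 92)))
  # 20 samples cannot support a 24-atom dictionary: the row fails, the
  # trainable row succeeds
  spec <- sweep_spec("n_samples", values = c(20, 1200), scale = 2, K = 24,
                     patch_size = 5, cascade_iter = 4, method = "cascade",
                     backprojection = FALSE, seed = 4)
  tab <- suppressMessages(run_sweep(spec, train, test,
                                    path = file.path(tempdir(), "sweep.csv")))
  expect_equal(tab$status, c("failed", "ok"))
  expect_true(all(is.na(tab[1, c("psnr_img1", "ssim_img1")])))
  csv <- readLines(file.path(tempdir(), "sweep.csv"))
  expect_match(csv[2], "-")            # dash convention for missing cells
})

test_that("single-value sweep equals one direct evaluation", {
  train <- list(make_phantom(phantom_spec(64, "mixed", seed = 93)))
  img <- make_phantom(phantom_spec(64, "mixed", seed = 94))
  spec <- sweep_spec("patch_size", values = 5, scale = 2, K = 16,
                     n_samples = 800, cascade_iter = 4, method = "cascade",
                     backprojection = FALSE, seed = 5)
  tab <- run_sweep(spec, train, list(img))
  pairs <- sample_training_pairs(train, 2, 5, 800, seed = 5)
  fit <- sr_train(pairs, "cascade", K = 16, lambda = 0.1, cascade_iter = 4,
                  seed = 5)
  rec <- sr_reconstruct(degrade(img, 2), fit,
                        sr_config(2, 5, 4, 0.1, backprojection = FALSE))
  expect_equal(tab$psnr_img1, psnr(img, rec$image))
  expect_equal(tab$ssim_img1, ssim(img, rec$image))
})
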