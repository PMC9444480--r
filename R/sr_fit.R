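#' Fit a coupled super-resolution dictionary
#'
#' The package's fitting front-end. `method = "cascade"` trains the
#' classical joint dictionary on the stacked HR/LR samples;
#' `method = "loss_optimized"` additionally refines that fit with the
#' bilevel separated-error procedure ([train_loss_optimized()]), which is
#' the method this package implements.
#'
#' @param pairs a screened [training_pairs()] set (from
#'   [sample_training_pairs()] or [sample_generative_pairs()]).
#' @param method `"loss_optimized"` (default) or `"cascade"`.
#' @param K atom count (full-size default 512; pass a smaller value for
#'   quick experiments).
#' @param lambda balance coefficient (default 0.1).
#' @param gamma HR/LR error weight for the bilevel stage.
#' @param cascade_iter alternations of the cascade stage.
#' @param outer_iter,lr_steps bilevel stage controls ([bilevel_config()]).
#' @param seed training seed (initialization).
#' @param random_init logical; initialize the bilevel stage from random
#'   unit atoms instead of the cascade fit (mainly for diagnostics).
#' @return an `sr_dict` (see [coupled_dictionary()]) with a training trace.
#'   For `method = "loss_optimized"` the cascade initialization is kept in
#'   component `cascade_init`.
#' @examples
#' cd0 <- make_coupled_dictionary(generative_spec(hr_dim = 16, lr_dim = 24,
#'                                                K = 20, seed = 7))
#' pairs <- sample_generative_pairs(cd0, generative_spec(hr_dim = 16,
#'   lr_dim = 24, K = 20, sparsity = 2, noise = 0.01, n_samples = 300,
#'   seed = 8))
#' fit <- sr_train(pairs, K = 20, lambda = 0.05, cascade_iter = 10,
#'                 outer_iter = 3, seed = 9)
#' print(fit)
#' @export
sr_train <- function(pairs, method = c("loss_optimized", "cascade"),
                     K = 512L, lambda = 0.1, gamma = 0.7,
                     cascade_iter = 30L, outer_iter = 20L, lr_steps = 5L,
                     seed = 1L, random_init = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(pairs, "training_pairs"))
  cas <- train_cascade(pairs, cascade_config(K = K, lambda = lambda,
                                             n_iter = cascade_iter,
                                             seed = seed))
  if (method == "cascade") return(cas)
  init <- if (random_init) {
    seeds <- derive_seeds(seed, 2)
    hr <- with_seed(seeds[1],
                    normalize_columns(matrix(rnorm(pairs$hr_dim * K),
                                             pairs$hr_dim)))
    lr <- with_seed(seeds[2],
                    normalize_columns(matrix(rnorm(pairs$lr_dim * K),
                                             pairs$lr_dim)))
    coupled_dictionary(hr, lr, scale = pairs$scale,
                       patch_size = pairs$patch_size,
                       overlap = cas$overlap, lambda = lambda,
                       provenance = "synthetic", seed = seed,
                       taps_id = pairs$taps_id)
  } else cas
  fit <- train_loss_optimized(pairs, init,
                              bilevel_config(gamma = gamma, lambda = lambda,
                                             outer_iter = outer_iter,
                                             lr_steps = lr_steps,
                                             seed = seed))
  fit$cascade_init <- cas
  fit
}
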