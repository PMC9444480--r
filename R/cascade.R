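#' Stack HR/LR training pairs into the cascade sample matrix
#'
#' The cascade (joint) training objective stacks each HR patch above its LR
#' feature vector, weighted by the reciprocal dimensions `1/N` and `1/M`, so
#' that both parts contribute comparably to one sparse-coding problem. The
#' returned recipe records `N` and `M` so a dictionary trained on the stack
#' can be split back into signal units.
#'
#' @param pairs a [training_pairs()] set.
#' @return list with `X_c` (`(N + M) x n` stacked matrix) and `recipe`
#'   (list with `N`, `M`, and the row weights `w_h = 1/N`, `w_l = 1/M`).
#' @export
build_cascade <- function(pairs) {
  if (!inherits(pairs, "training_pairs")) stopf("pairs must be training_pairs")
  if (pairs$n < 1) stopf("empty pair set")
  N <- pairs$hr_dim; M <- pairs$lr_dim
  list(X_c = rbind(pairs$hr / N, pairs$lr / M),
       recipe = list(N = N, M = M, w_h = 1 / N, w_l = 1 / M))
}

# Split a cascade-trained dictionary back into coupled HR/LR parts. Both
# parts of each atom are divided by the same factor (the larger of the two
# unscaled norms, when above 1), which keeps the shared-code coupling intact
# while enforcing unit-ball column norms.
split_cascade_dictionary <- function(D_c, recipe) {
  N <- recipe$N; M <- recipe$M
  H <- D_c[seq_len(N), , drop = FALSE] / recipe$w_h
  L <- D_c[N + seq_len(M), , drop = FALSE] / recipe$w_l
  s <- pmax(1, pmax(col_norms(H), col_norms(L)))
  list(hr = sweep(H, 2, s, "/"), lr = sweep(L, 2, s, "/"))
}

#' Cascade configuration
#'
#' @param K atom count (default 512, the method's tuned dictionary size).
#' @param lambda balance coefficient (default 0.1); the penalty actually
#'   applied to the stacked problem is `lambda * (1/N + 1/M)`.
#' @param n_iter training alternations.
#' @param seed initialization seed.
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(K = 512L, lambda = 0.1, n_iter = 30L, seed = 1L) {
  if (K < 2) stopf("K must be >= 2")
  structure(list(K = as.integer(K), lambda = lambda,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "cascade_config")
}

#' Train a coupled dictionary by the cascade objective
#'
#' The classical joint training baseline: [train_dictionary()] is run on the
#' stacked sample matrix of [build_cascade()] with effective penalty
#' `lambda * (1/N + 1/M)`, and the learned stacked atoms are split back into
#' coupled HR and LR parts (jointly rescaled onto the unit ball).
#'
#' @param pairs a screened [training_pairs()] set.
#' @param config a [cascade_config()].
#' @return an `sr_dict` with provenance `"cascade"` and a training trace
#'   (iteration, objective, fit, sparsity).
#' @seealso [train_loss_optimized()], [sr_train()]
#' @export
train_cascade <- function(pairs, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  cas <- build_cascade(pairs)
  lambda_eff <- config$lambda * (cas$recipe$w_h + cas$recipe$w_l)
  d <- train_dictionary(cas$X_c, config$K, lambda_eff,
                        n_iter = config$n_iter, seed = config$seed)
  parts <- split_cascade_dictionary(d$atoms, cas$recipe)
  tr <- attr(d, "trace")
  trace <- data.frame(iteration = tr$iteration, loss = tr$objective,
                      fit = tr$fit, R_x = NA_real_, R_y = NA_real_,
                      sparsity = tr$sparsity, step = NA_real_)
  coupled_dictionary(parts$hr, parts$lr, scale = pairs$scale,
                     patch_size = pairs$patch_size,
                     overlap = if (is.na(pairs$patch_size)) NA
                               else pairs$patch_size - 1L,
                     lambda = config$lambda, provenance = "cascade",
                     seed = config$seed, taps_id = pairs$taps_id,
                     trace = trace)
}
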