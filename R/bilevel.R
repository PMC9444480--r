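#' Bilevel training configuration
#'
#' Controls for the loss-optimized coupled training, which alternates a
#' closed-form high-resolution dictionary update with projected gradient
#' steps on the low-resolution dictionary, the gradient coming from implicit
#' differentiation of the lasso optimality conditions.
#'
#' @param gamma HR/LR error weight in (0, 1\]; the joint loss is
#'   `mean_i 0.5 * (gamma * ||D_h c_i - x_i||^2 + (1 - gamma) * ||D_l c_i - y_i||^2)`.
#'   Default 0.7: the method exists to push down the HR reconstruction
#'   error, so the HR term is weighted above one half.
#' @param lambda sparse-coding penalty of the lower-level problem.
#' @param outer_iter number of outer alternations (default 20).
#' @param lr_steps LR-dictionary gradient steps per outer iteration.
#' @param step0 initial line-search step size.
#' @param shrink backtracking shrink factor in (0, 1).
#' @param min_step smallest step tried before giving up on a descent step.
#' @param rel_tol early-exit threshold on the relative loss change.
#' @param seed seed recorded in the trace.
#' @return object of class `bilevel_config`.
#' @export
bilevel_config <- function(gamma = 0.7, lambda = 0.1, outer_iter = 20L,
                           lr_steps = 5L, step0 = 1, shrink = 0.5,
                           min_step = 1e-8, rel_tol = 1e-4, seed = 1L) {
  if (gamma <= 0 || gamma > 1) stopf("gamma must lie in (0, 1]")
  if (shrink <= 0 || shrink >= 1) stopf("shrink must lie in (0, 1)")
  structure(list(gamma = gamma, lambda = lambda,
                 outer_iter = as.integer(outer_iter),
                 lr_steps = as.integer(lr_steps), step0 = step0,
                 shrink = shrink, min_step = min_step, rel_tol = rel_tol,
                 seed = as.integer(seed)),
            class = "bilevel_config")
}

#' Joint separated-error loss of a coupled dictionary
#'
#' Codes every LR sample against the LR dictionary
#' (`c_i = argmin ||y_i - D_l a||^2 + lambda ||a||_1`) and evaluates the
#' gamma-weighted mean of the separate HR and LR reconstruction residuals:
#' `L = mean_i 0.5 * (gamma * R_x_i + (1 - gamma) * R_y_i)` with
#' `R_x_i = ||D_h c_i - x_i||^2`, `R_y_i = ||D_l c_i - y_i||^2`.
#'
#' @param cd an `sr_dict` (coupled dictionary).
#' @param pairs a [training_pairs()] set with matching dimensions.
#' @param gamma HR/LR weight in (0, 1\].
#' @param lambda lower-level sparse-coding penalty.
#' @param codes optional precomputed `K x n` code matrix (skips the solve).
#' @return list with `L`, `R_x`, `R_y` (means over samples), `sparsity`
#'   (mean nonzeros per code), and `codes`.
#' @export
joint_loss <- function(cd, pairs, gamma, lambda, codes = NULL) {
  stopifnot(inherits(cd, "sr_dict"), inherits(pairs, "training_pairs"))
  if (cd$hr_dim != pairs$hr_dim || cd$lr_dim != pairs$lr_dim)
    stopf("dictionary dims (%d, %d) do not match pair dims (%d, %d)",
          cd$hr_dim, cd$lr_dim, pairs$hr_dim, pairs$lr_dim)
  if (is.null(codes))
    codes <- code_matrix(cd$lr, pairs$lr, lambda, warn = FALSE)
  Rx <- mean(colSums((cd$hr$atoms %*% codes - pairs$hr)^2))
  Ry <- mean(colSums((cd$lr$atoms %*% codes - pairs$lr)^2))
  list(L = 0.5 * (gamma * Rx + (1 - gamma) * Ry), R_x = Rx, R_y = Ry,
       sparsity = mean(colSums(codes != 0)), codes = codes)
}

#' Closed-form high-resolution dictionary update
#'
#' With the codes fixed (they depend only on the LR dictionary), the HR part
#' minimizes `sum_i 0.5 ||D_h c_i - x_i||^2` subject to unit-ball columns:
#' solved as regularized least squares `X C' (C C' + eps I)^-1` (eps = 1e-8)
#' with over-norm columns scaled down onto the unit sphere. The update is
#' returned only when it does not increase the HR residual; an all-zero code
#' matrix leaves the dictionary unchanged with a warning (the objective is
#' then constant in the HR part).
#'
#' @inheritParams joint_loss
#' @return the new HR [dictionary()].
#' @export
update_hr_dictionary <- function(cd, pairs, lambda, codes = NULL) {
  stopifnot(inherits(cd, "sr_dict"))
  if (is.null(codes))
    codes <- code_matrix(cd$lr, pairs$lr, lambda, warn = FALSE)
  if (all(codes == 0)) {
    warnf("all sparse codes are zero; HR dictionary left unchanged")
    return(cd$hr)
  }
  G <- codes %*% t(codes)
  diag(G) <- diag(G) + 1e-8
  D_new <- clip_columns_to_unit_ball(t(solve(G, codes %*% t(pairs$hr))))
  rx_old <- mean(colSums((cd$hr$atoms %*% codes - pairs$hr)^2))
  rx_new <- mean(colSums((D_new %*% codes - pairs$hr)^2))
  if (rx_new > rx_old + 1e-12) return(cd$hr)   # clipping made things worse
  dictionary(D_new, role = "hr", scale = cd$scale, geometry = cd$hr$geometry)
}

#' Implicit-differentiation gradient of the joint loss in the LR dictionary
#'
#' Computes `dL/dD_l` holding each sample's active set fixed. Per sample the
#' gradient is the direct term `(1 - gamma) (D_l c - y) c'` plus a chain
#' term from implicitly differentiating the lasso stationarity system
#' restricted to the active set: with `A = D~' D~` (the active-column Gram),
#' `u = A^-1 g~` (the upper-level gradient in the active code), and
#' `r = y - D~ c~` the lasso residual, the chain contribution to the active
#' columns is `r u' - D~ u c~'`. Samples whose active Gram matrix is
#' numerically singular are skipped (the implicit function theorem requires
#' a unique, locally smooth solution); their count is reported in the
#' `"n_skipped"` attribute.
#'
#' @inheritParams joint_loss
#' @return `M x K` gradient matrix (mean over non-skipped samples), with
#'   attribute `n_skipped`.
#' @export
grad_lr_dictionary <- function(cd, pairs, gamma, lambda, codes = NULL) {
  stopifnot(inherits(cd, "sr_dict"))
  if (is.null(codes))
    codes <- code_matrix(cd$lr, pairs$lr, lambda, warn = FALSE)
  Dl <- cd$lr$atoms; Dh <- cd$hr$atoms
  M <- nrow(Dl); K <- ncol(Dl)
  n <- ncol(codes)
  Ex <- Dh %*% codes - pairs$hr     # HR residuals, all samples
  Ey <- Dl %*% codes - pairs$lr     # LR residuals
  chain_sum <- matrix(0, M, K)
  used <- rep(TRUE, n)
  for (i in seq_len(n)) {
    c_i <- codes[, i]
    omega <- which(c_i != 0)
    if (length(omega) == 0) next    # empty active set: chain term vanishes
    Dt <- Dl[, omega, drop = FALSE]
    A <- crossprod(Dt)
    if (rcond(A) < 1e-10) { used[i] <- FALSE; next }
    gt <- gamma * crossprod(Dh[, omega, drop = FALSE], Ex[, i]) +
      (1 - gamma) * crossprod(Dt, Ey[, i])
    u <- solve(A, gt)
    r <- pairs$lr[, i] - Dt %*% c_i[omega]
    chain_sum[, omega] <- chain_sum[, omega] +
      r %*% t(u) - (Dt %*% u) %*% t(c_i[omega])
  }
  n_used <- sum(used)
  n_skipped <- n - n_used
  if (n_used == 0L)
    stopf("every sample's active Gram matrix is singular; gradient undefined")
  if (n_skipped > 0L)
    warnf("skipped %d of %d samples with singular active-set Gram matrices",
          n_skipped, n)
  # direct term over retained samples in one product
  direct <- (1 - gamma) *
    (Ey[, used, drop = FALSE] %*% t(codes[, used, drop = FALSE]))
  G <- (direct + chain_sum) / n_used
  attr(G, "n_skipped") <- n_skipped
  G
}

#' One projected line-search step on the LR dictionary
#'
#' Takes a backtracking step along the negative implicit gradient: the
#' candidate `D_l - step * G` is projected column-wise onto the unit ball
#' and accepted only if the joint loss (with codes recomputed) strictly
#' decreases; otherwise the step shrinks. At the minimum step the LR
#' dictionary is returned unchanged.
#'
#' @inheritParams joint_loss
#' @param config a [bilevel_config()].
#' @param step0 initial step (defaults to `config$step0`).
#' @param state optional cached list with `codes`, `loss` (from a previous
#'   [joint_loss()] call) to avoid recomputation.
#' @return list with `lr` (new LR [dictionary()]), `step` (accepted step, or
#'   0 when no descent step was found), and `loss` (the new [joint_loss()]
#'   evaluation).
#' @export
update_lr_dictionary <- function(cd, pairs, config = bilevel_config(),
                                 step0 = NULL, state = NULL) {
  stopifnot(inherits(cd, "sr_dict"), inherits(config, "bilevel_config"))
  gamma <- config$gamma; lambda <- config$lambda
  if (is.null(state))
    state <- joint_loss(cd, pairs, gamma, lambda)
  G <- grad_lr_dictionary(cd, pairs, gamma, lambda, codes = state$codes)
  attr(G, "n_skipped") <- NULL
  step <- step0 %||% config$step0
  if (all(G == 0))
    return(list(lr = cd$lr, step = step, loss = state))
  while (step >= config$min_step) {
    cand <- clip_columns_to_unit_ball(cd$lr$atoms - step * G)
    cd_cand <- cd
    cd_cand$lr <- dictionary(cand, role = "lr", scale = cd$scale,
                             geometry = cd$lr$geometry)
    new <- joint_loss(cd_cand, pairs, gamma, lambda)
    if (new$L < state$L) {
      return(list(lr = cd_cand$lr, step = step, loss = new))
    }
    step <- step * config$shrink
  }
  list(lr = cd$lr, step = 0, loss = state)
}

#' Loss-optimized (bilevel) coupled dictionary training
#'
#' The method's training procedure: starting from an initial coupled
#' dictionary (normally the cascade fit), alternate (1) the closed-form HR
#' dictionary update at fixed codes and (2) `lr_steps` projected implicit-
#' gradient steps on the LR dictionary, for `outer_iter` rounds or until the
#' relative loss change drops below `rel_tol`. The separated-error joint
#' loss is non-increasing over accepted iterations by construction.
#'
#' @param pairs a screened [training_pairs()] set.
#' @param init initial `sr_dict` (typically from [train_cascade()]).
#' @param config a [bilevel_config()].
#' @return an `sr_dict` with provenance `"loss_optimized"` and a trace data
#'   frame (iteration, loss, R_x, R_y, sparsity, step); iteration 0 records
#'   the initialization.
#' @export
train_loss_optimized <- function(pairs, init, config = bilevel_config()) {
  stopifnot(inherits(init, "sr_dict"), inherits(config, "bilevel_config"))
  cd <- init
  cur <- joint_loss(cd, pairs, config$gamma, config$lambda)
  trace <- data.frame(iteration = 0L, loss = cur$L, R_x = cur$R_x,
                      R_y = cur$R_y, sparsity = cur$sparsity, step = NA_real_)
  step <- config$step0
  for (it in seq_len(config$outer_iter)) {
    prev_L <- cur$L
    # HR step: codes unchanged (they depend only on D_l), residual guarded
    cd$hr <- update_hr_dictionary(cd, pairs, config$lambda, codes = cur$codes)
    Rx <- mean(colSums((cd$hr$atoms %*% cur$codes - pairs$hr)^2))
    cur$R_x <- Rx
    cur$L <- 0.5 * (config$gamma * Rx + (1 - config$gamma) * cur$R_y)
    # LR steps: implicit-gradient descent with backtracking
    last_step <- 0
    for (s in seq_len(config$lr_steps)) {
      res <- update_lr_dictionary(cd, pairs, config,
                                  step0 = min(config$step0,
                                              max(step * 2, config$min_step)),
                                  state = cur)
      cd$lr <- res$lr
      cur <- res$loss
      if (res$step == 0) break
      step <- res$step
      last_step <- res$step
    }
    trace <- rbind(trace, data.frame(iteration = it, loss = cur$L,
                                     R_x = cur$R_x, R_y = cur$R_y,
                                     sparsity = cur$sparsity,
                                     step = last_step))
    if (prev_L - cur$L < config$rel_tol * max(prev_L, .Machine$double.eps))
      break
  }
  cd$provenance <- "loss_optimized"
  cd$gamma <- config$gamma
  cd$lambda <- config$lambda
  cd$trace <- trace
  cd
}
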