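#' Dictionary constructor
#'
#' A dictionary is a matrix with one atom (elementary signal pattern) per
#' column. Trained dictionaries are overcomplete (more atoms than signal
#' dimensions) and have column norms at most 1; small test fixtures may be
#' undercomplete.
#'
#' @param atoms numeric matrix, `n x K`, one atom per column.
#' @param role one of `"single"`, `"hr"`, `"lr"`.
#' @param scale integer super-resolution factor this dictionary was trained
#'   for, or `NA` for generic fixtures.
#' @param geometry optional list describing the patch geometry
#'   (`patch_size`, `overlap`) the atoms correspond to.
#' @return an object of class `dictionary`.
#' @export
dictionary <- function(atoms, role = c("single", "hr", "lr"), scale = NA,
                       geometry = NULL) {
  role <- match.arg(role)
  if (!is.matrix(atoms) || !is.numeric(atoms)) stopf("atoms must be a matrix")
  if (!all(is.finite(atoms))) stopf("dictionary atoms must be finite")
  nrm <- col_norms(atoms)
  if (any(nrm > 1 + 1e-9))
    stopf("dictionary column norms must be <= 1 (max %.6g)", max(nrm))
  structure(list(atoms = atoms, n = nrow(atoms), K = ncol(atoms),
                 role = role, scale = scale, geometry = geometry),
            class = "dictionary")
}

#' @export
print.dictionary <- function(x, ...) {
  cat(sprintf("<dictionary> %d atoms of dimension %d (role: %s%s)\n",
              x$K, x$n, x$role,
              if (is.na(x$scale)) "" else sprintf(", scale x%d", x$scale)))
  invisible(x)
}

as_atom_matrix <- function(D) {
  if (inherits(D, "dictionary")) D$atoms
  else if (is.matrix(D)) D
  else stopf("expected a dictionary or atom matrix")
}

#' Sparse-coding solver configuration
#'
#' @param lambda nonnegative L1 penalty weight balancing representation
#'   error against sparsity.
#' @param tol stationarity tolerance: convergence is declared when no
#'   coefficient moves by more than `tol` in a full sweep.
#' @param max_iter iteration cap (coordinate-descent sweeps).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(lambda = 0.1, tol = 1e-6, max_iter = 1000L) {
  if (lambda < 0) stopf("lambda must be >= 0")
  if (tol <= 0) stopf("tol must be > 0")
  if (max_iter < 1) stopf("max_iter must be >= 1")
  structure(list(lambda = lambda, tol = tol, max_iter = as.integer(max_iter)),
            class = "solver_config")
}

#' Penalized sparse-representation objective
#'
#' The objective minimized by the sparse coder,
#' `||x - D alpha||_2^2 + lambda * ||alpha||_1` (no 1/2 factor on the
#' quadratic term).
#'
#' @param D dictionary (or atom matrix).
#' @param x signal vector of length `nrow(D)`.
#' @param alpha coefficient vector of length `ncol(D)`, or a `sparse_code`.
#' @param lambda L1 penalty weight.
#' @return scalar objective value.
#' @export
lasso_objective <- function(D, x, alpha, lambda) {
  A <- as_atom_matrix(D)
  if (inherits(alpha, "sparse_code")) alpha <- alpha$coefficients
  if (length(x) != nrow(A)) stopf("x has length %d, expected %d",
                                  length(x), nrow(A))
  if (length(alpha) != ncol(A)) stopf("alpha has length %d, expected %d",
                                      length(alpha), ncol(A))
  sum((x - A %*% alpha)^2) + lambda * sum(abs(alpha))
}

# Batch coordinate-descent solve returning the K x n coefficient matrix.
# Workhorse shared by training and reconstruction; warnings about
# non-convergence are summarized, not raised per column.
code_matrix <- function(D, X, lambda, tol = 1e-6, max_iter = 1000L,
                        warn = TRUE) {
  A <- as_atom_matrix(D)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != nrow(A))
    stopf("signal dimension %d does not match dictionary dimension %d",
          nrow(X), nrow(A))
  res <- .cd_lasso_cpp(A, X, lambda, tol, as.integer(max_iter), FALSE)
  nbad <- sum(res$converged == 0)
  if (warn && nbad > 0)
    warnf("sparse coder did not converge for %d of %d signals within %d sweeps",
          nbad, ncol(X), max_iter)
  attr(res$coef, "converged") <- as.logical(res$converged)
  res$coef
}

#' Sparse-code one signal
#'
#' Solves `min_alpha ||x - D alpha||_2^2 + lambda ||alpha||_1` by cyclic
#' coordinate descent with exact scalar soft-threshold updates. If the
#' iteration cap is reached before stationarity the final iterate is
#' returned with `converged = FALSE` and a warning.
#'
#' @param D dictionary (or atom matrix).
#' @param x signal vector.
#' @param config a [solver_config()] (or pass `lambda` directly).
#' @param lambda,tol,max_iter shortcut scalar overrides of `config`.
#' @return object of class `sparse_code`: `coefficients` (length `K`),
#'   `active_set` (indices of nonzeros), `converged`, `iters`.
#' @export
sparse_code <- function(D, x, config = solver_config(), lambda = NULL,
                        tol = NULL, max_iter = NULL) {
  cfg <- config
  if (!is.null(lambda)) cfg$lambda <- lambda
  if (!is.null(tol)) cfg$tol <- tol
  if (!is.null(max_iter)) cfg$max_iter <- as.integer(max_iter)
  a <- code_matrix(D, matrix(x, ncol = 1), cfg$lambda, cfg$tol, cfg$max_iter,
                   warn = FALSE)
  conv <- attr(a, "converged")
  if (!conv)
    warnf("sparse coder did not converge within %d sweeps", cfg$max_iter)
  structure(list(coefficients = as.numeric(a),
                 active_set = which(a != 0),
                 converged = conv, lambda = cfg$lambda),
            class = "sparse_code")
}

#' Sparse-code a batch of signals
#'
#' Column-wise application of [sparse_code()]; results are returned in input
#' order and are identical to independent single calls.
#'
#' @param D dictionary (or atom matrix).
#' @param X matrix of signals, one per column.
#' @param config a [solver_config()].
#' @return list of `sparse_code` objects, one per column.
#' @export
sparse_code_batch <- function(D, X, config = solver_config()) {
  if (!is.matrix(X) || ncol(X) < 1) stopf("X must be a matrix with >= 1 column")
  A <- code_matrix(D, X, config$lambda, config$tol, config$max_iter)
  conv <- attr(A, "converged")
  lapply(seq_len(ncol(X)), function(j) {
    structure(list(coefficients = A[, j], active_set = which(A[, j] != 0),
                   converged = conv[j], lambda = config$lambda),
              class = "sparse_code")
  })
}
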