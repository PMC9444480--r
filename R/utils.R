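#' @keywords internal
"_PACKAGE"

#' @useDynLib dictSR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif var coef predict
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a stream of sub-seeds from one master seed, staying inside the
# 32-bit signed integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Column 2-norms of a matrix.
col_norms <- function(M) sqrt(colSums(M^2))

# Scale any column with norm > 1 down onto the unit sphere (projection of
# each column onto the unit ball).
clip_columns_to_unit_ball <- function(M) {
  nrm <- col_norms(M)
  over <- nrm > 1
  if (any(over)) M[, over] <- sweep(M[, over, drop = FALSE], 2, nrm[over], "/")
  M
}

# Normalize all columns to unit norm (zero columns left untouched).
normalize_columns <- function(M) {
  nrm <- col_norms(M)
  nz <- nrm > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
  M
}
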