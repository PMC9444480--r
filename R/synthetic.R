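#' Phantom image specification
#'
#' Seeded generators for the test imagery the experiments run on:
#' piecewise-smooth regions with sharp boundaries and fine texture,
#' emulating the structural content of anatomical grayscale images without
#' any external data.
#'
#' @param size image side length (>= 32).
#' @param kind `"mixed"` (ellipses plus texture), `"ellipses"`, `"texture"`
#'   (band-limited noise), or `"edges"` (random oriented steps).
#' @param seed integer seed; the output is a deterministic function of the
#'   spec.
#' @param contrast length-2 intensity range the phantom is mapped into; a
#'   collapsed range yields a constant image (allowed, for degenerate
#'   tests).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 128L, kind = c("mixed", "ellipses",
                                               "texture", "edges"),
                         seed = 1L, contrast = c(0.05, 0.95)) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 32) stopf("phantom size must be >= 32")
  if (length(contrast) != 2 || any(contrast < 0) || any(contrast > 1) ||
      contrast[2] < contrast[1])
    stopf("contrast must be an increasing pair inside [0, 1]")
  structure(list(size = size, kind = kind, seed = as.integer(seed),
                 contrast = contrast), class = "phantom_spec")
}

map_contrast <- function(img, contrast) {
  rg <- range(img)
  if (rg[2] > rg[1]) img <- (img - rg[1]) / (rg[2] - rg[1])
  else img <- img * 0
  contrast[1] + img * (contrast[2] - contrast[1])
}

phantom_ellipses <- function(n, n_ell = 9L) {
  xs <- matrix(rep(seq_len(n), each = n), n) / n   # column coordinate
  ys <- matrix(rep(seq_len(n), times = n), n) / n  # row coordinate
  img <- matrix(0, n, n)
  for (e in seq_len(n_ell)) {
    cx <- runif(1, 0.15, 0.85); cy <- runif(1, 0.15, 0.85)
    a <- runif(1, 0.06, 0.35); b <- runif(1, 0.06, 0.35)
    th <- runif(1, 0, pi); lev <- runif(1, -1, 1)
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    img <- img + lev * ((u / a)^2 + (v / b)^2 <= 1)
  }
  img
}

phantom_texture <- function(n, smooth = 1.2) {
  noise <- matrix(rnorm(n * n), n)
  g <- gaussian_window(7L, smooth)
  correlate2d(correlate2d(noise, matrix(g, nrow = 1)), matrix(g, ncol = 1))
}

phantom_edges <- function(n, n_steps = 6L) {
  xs <- matrix(rep(seq_len(n), each = n), n) / n
  ys <- matrix(rep(seq_len(n), times = n), n) / n
  img <- matrix(0, n, n)
  for (e in seq_len(n_steps)) {
    th <- runif(1, 0, 2 * pi); off <- runif(1, 0.2, 0.8)
    lev <- runif(1, 0.3, 1) * sample(c(-1, 1), 1)
    img <- img + lev * ((xs * cos(th) + ys * sin(th)) > off)
  }
  img
}

#' Generate a phantom image
#'
#' @param spec a [phantom_spec()].
#' @return image plane of dimension `size x size` inside the spec's
#'   contrast range, with non-trivial gradient energy (except for a
#'   deliberately collapsed contrast range).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  img <- with_seed(spec$seed, switch(spec$kind,
    ellipses = phantom_ellipses(n),
    texture = phantom_texture(n),
    edges = phantom_edges(n),
    mixed = {
      base <- phantom_ellipses(n)
      tex <- phantom_texture(n)
      map_contrast(base, c(0, 1)) + 0.15 * map_contrast(tex, c(-1, 1))
    }))
  as_image_plane(map_contrast(img, spec$contrast))
}

#' Generative coupled-dictionary specification
#'
#' Parameters of the generative model used for recovery experiments:
#' samples are `x = D_h c + noise`, `y = D_l c + noise` with a shared
#' `sparsity`-sparse standard-normal code `c` against a random unit-norm
#' coupled dictionary.
#'
#' @param hr_dim,lr_dim signal dimensions `N`, `M`.
#' @param K atom count.
#' @param sparsity nonzeros per code (`<= K`).
#' @param noise additive Gaussian noise standard deviation.
#' @param n_samples number of samples to draw.
#' @param seed integer seed.
#' @return object of class `generative_spec`.
#' @export
generative_spec <- function(hr_dim = 25L, lr_dim = 100L, K = 32L,
                            sparsity = 3L, noise = 0.01, n_samples = 2000L,
                            seed = 1L) {
  if (sparsity > K) stopf("sparsity must be <= K")
  if (noise < 0) stopf("noise must be >= 0")
  structure(list(hr_dim = as.integer(hr_dim), lr_dim = as.integer(lr_dim),
                 K = as.integer(K), sparsity = as.integer(sparsity),
                 noise = noise, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "generative_spec")
}

#' Draw a random coupled dictionary
#'
#' Both parts have independent standard-normal atoms normalized to exactly
#' unit column norm; atom `k` of the two parts is coupled by index.
#'
#' @param spec a [generative_spec()].
#' @return an `sr_dict` with provenance `"synthetic"`.
#' @export
make_coupled_dictionary <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  seeds <- derive_seeds(spec$seed, 2)
  hr <- with_seed(seeds[1],
                  normalize_columns(matrix(rnorm(spec$hr_dim * spec$K),
                                           spec$hr_dim)))
  lr <- with_seed(seeds[2],
                  normalize_columns(matrix(rnorm(spec$lr_dim * spec$K),
                                           spec$lr_dim)))
  coupled_dictionary(hr, lr, provenance = "synthetic", seed = spec$seed)
}

#' Sample matched pairs from a generative coupled dictionary
#'
#' Each sample draws a support of size `sparsity` uniformly without
#' replacement, standard-normal coefficients on it, and forms
#' `x = D_h c + noise`, `y = D_l c + noise`. The true codes are attached as
#' attribute `"codes"` for recovery scoring.
#'
#' @param cd an `sr_dict` (e.g. from [make_coupled_dictionary()]).
#' @param spec a [generative_spec()] (dims must match `cd`).
#' @return a [training_pairs()] set with attribute `"codes"` (`K x n`).
#' @export
sample_generative_pairs <- function(cd, spec) {
  stopifnot(inherits(cd, "sr_dict"), inherits(spec, "generative_spec"))
  if (cd$hr_dim != spec$hr_dim || cd$lr_dim != spec$lr_dim ||
      cd$K != spec$K)
    stopf("spec dims (%d, %d, K=%d) do not match the dictionary (%d, %d, K=%d)",
          spec$hr_dim, spec$lr_dim, spec$K, cd$hr_dim, cd$lr_dim, cd$K)
  n <- spec$n_samples
  C <- with_seed(spec$seed + 1L, {
    C <- matrix(0, spec$K, n)
    for (j in seq_len(n))
      C[sample.int(spec$K, spec$sparsity), j] <- rnorm(spec$sparsity)
    C
  })
  X <- cd$hr$atoms %*% C
  Y <- cd$lr$atoms %*% C
  if (spec$noise > 0) {
    X <- X + with_seed(spec$seed + 2L,
                       matrix(rnorm(length(X), sd = spec$noise), nrow(X)))
    Y <- Y + with_seed(spec$seed + 3L,
                       matrix(rnorm(length(Y), sd = spec$noise), nrow(Y)))
  }
  out <- training_pairs(X, Y, seed = spec$seed)
  attr(out, "codes") <- C
  out
}

#' Greedy atom matching by absolute cosine similarity
#'
#' Scores how well a trained dictionary recovers the atoms of a generator:
#' the |cosine| matrix between (normalized) atoms is matched greedily —
#' repeatedly pairing the globally most similar unmatched atoms — and the
#' per-generator-atom similarities are returned.
#'
#' @param trained,generator atom matrices (or `dictionary` objects) with
#'   equal row dimension.
#' @param threshold similarity counted as "recovered".
#' @return list with `cosines` (one per generator atom, matched greedily),
#'   `pairs` (matched trained index per generator atom), and `rate` (the
#'   fraction of generator atoms with |cosine| >= `threshold`).
#' @export
match_atoms <- function(trained, generator, threshold = 0.95) {
  A <- normalize_columns(as_atom_matrix(trained))
  B <- normalize_columns(as_atom_matrix(generator))
  if (nrow(A) != nrow(B)) stopf("atom dimensions differ")
  S <- abs(crossprod(B, A))           # generator x trained
  cos <- numeric(ncol(B)); pair <- integer(ncol(B))
  for (step in seq_len(min(ncol(A), ncol(B)))) {
    ij <- arrayInd(which.max(S), dim(S))
    cos[ij[1]] <- S[ij[1], ij[2]]
    pair[ij[1]] <- ij[2]
    S[ij[1], ] <- -1
    S[, ij[2]] <- -1
  }
  list(cosines = cos, pairs = pair, rate = mean(cos >= threshold))
}
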