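# Serialization: one documented container format shared by pair sets and
# dictionaries. A file is a single-line JSON metadata header (terminated by
# a newline) followed by the declared matrices as little-endian float32,
# column-major, in header order. Float32 storage is part of the format and
# rounds values to ~7 significant digits.

write_binary_container <- function(path, meta, matrices) {
  stopifnot(is.list(matrices), length(names(matrices)) == length(matrices))
  meta$format <- "dictSR-bin"
  meta$version <- 1L
  meta$matrices <- lapply(names(matrices), function(nm) {
    list(name = nm, nrow = nrow(matrices[[nm]]), ncol = ncol(matrices[[nm]]))
  })
  con <- file(path, "wb")
  on.exit(close(con))
  header <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(as.character(header), "\n")), con)
  for (M in matrices)
    writeBin(as.vector(M), con, size = 4L, endian = "little")
  invisible(path)
}

read_binary_container <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))[1]
  if (is.na(nl)) stopf("'%s' is not a dictSR container (no header)", path)
  meta <- jsonlite::fromJSON(rawToChar(raw[seq_len(nl - 1L)]),
                             simplifyDataFrame = FALSE)
  if (!identical(meta$format, "dictSR-bin"))
    stopf("'%s' is not a dictSR container", path)
  offset <- nl
  matrices <- list()
  for (m in meta$matrices) {
    len <- m$nrow * m$ncol
    vals <- readBin(raw[(offset + 1):(offset + 4L * len)], "numeric",
                    n = len, size = 4L, endian = "little")
    matrices[[m$name]] <- matrix(vals, m$nrow, m$ncol)
    offset <- offset + 4L * len
  }
  meta$matrices <- NULL
  list(meta = meta, matrices = matrices)
}

#' Write / read a training pair set
#'
#' Pair sets are stored as a JSON metadata header (dimensions, scale, patch
#' size, taps, seed) followed by the HR and LR matrices as little-endian
#' float32 (column-major). Values therefore round-trip at float32 precision.
#'
#' @param pairs a [training_pairs()] set.
#' @param path file path.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns the
#'   `training_pairs` object.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "training_pairs"))
  write_binary_container(path,
    list(kind = "training_pairs", hr_dim = pairs$hr_dim,
         lr_dim = pairs$lr_dim, scale = pairs$scale,
         patch_size = pairs$patch_size, seed = pairs$seed,
         taps_id = pairs$taps_id),
    list(hr = pairs$hr, lr = pairs$lr))
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  z <- read_binary_container(path)
  if (!identical(z$meta$kind, "training_pairs"))
    stopf("'%s' does not contain a training pair set", path)
  training_pairs(z$matrices$hr, z$matrices$lr,
                 scale = z$meta$scale %||% NA,
                 patch_size = z$meta$patch_size %||% NA,
                 seed = z$meta$seed %||% NA,
                 taps_id = z$meta$taps_id %||% "grad12")
}

#' Write / read a single dictionary
#'
#' @param dict a [dictionary()].
#' @param path file path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   the `dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "dictionary"))
  write_binary_container(path,
    list(kind = "dictionary", n = dict$n, K = dict$K, role = dict$role,
         scale = dict$scale, geometry = dict$geometry),
    list(atoms = dict$atoms))
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  z <- read_binary_container(path)
  if (!identical(z$meta$kind, "dictionary"))
    stopf("'%s' does not contain a dictionary", path)
  # float32 storage can push stored unit norms epsilon above 1; renormalize
  atoms <- clip_columns_to_unit_ball(z$matrices$atoms)
  dictionary(atoms, role = z$meta$role %||% "single",
             scale = z$meta$scale %||% NA, geometry = z$meta$geometry)
}

#' Write / read a coupled dictionary (fitted `sr_dict` object)
#'
#' One container holds both dictionary parts plus the metadata needed to
#' reuse the fit: atom count, dimensions, scale, patch geometry, training
#' penalty and weighting, provenance and seed.
#'
#' @param object an `sr_dict` fit (see [sr_train()]) or [coupled_dictionary()].
#' @param path file path.
#' @return `write_sr_dict` returns `path` invisibly; `read_sr_dict` the
#'   restored `sr_dict` object (training trace is not stored; export it
#'   separately with [write_trace()]).
#' @export
write_sr_dict <- function(object, path) {
  stopifnot(inherits(object, "sr_dict"))
  write_binary_container(path,
    list(kind = "coupled_dictionary", K = object$K, hr_dim = object$hr_dim,
         lr_dim = object$lr_dim, scale = object$scale,
         patch_size = object$patch_size, overlap = object$overlap,
         lambda = object$lambda, gamma = object$gamma,
         provenance = object$provenance, seed = object$seed,
         taps_id = object$taps_id),
    list(hr = object$hr$atoms, lr = object$lr$atoms))
}

#' @rdname write_sr_dict
#' @export
read_sr_dict <- function(path) {
  z <- read_binary_container(path)
  if (!identical(z$meta$kind, "coupled_dictionary"))
    stopf("'%s' does not contain a coupled dictionary", path)
  m <- z$meta
  coupled_dictionary(clip_columns_to_unit_ball(z$matrices$hr),
                     clip_columns_to_unit_ball(z$matrices$lr),
                     scale = m$scale %||% NA,
                     patch_size = m$patch_size %||% NA,
                     overlap = m$overlap %||% NA,
                     lambda = m$lambda %||% NA, gamma = m$gamma %||% NA,
                     provenance = m$provenance %||% "unknown",
                     seed = m$seed %||% NA,
                     taps_id = m$taps_id %||% "grad12")
}

#' Export a training trace as CSV
#'
#' @param trace a `training_trace` data frame (component `trace` of a fit).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
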