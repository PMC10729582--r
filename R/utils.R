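# Shared low-level helpers around the compiled kernels.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components of a binary array
#'
#' @param mask logical array, 2D or 3D.
#' @param connectivity `"full"` (8-neighbourhood in 2D, 26 in 3D, the default)
#'   or `"face"` (4 / 6).
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.logical(mask), length(dim(mask)) %in% c(2L, 3L))
  cc_label_cpp(mask, dim(mask), if (connectivity == "full") 2L else 1L)
}

#' Euclidean distance transform with anisotropic sampling
#'
#' Distance in physical units from every voxel to the nearest `TRUE` voxel.
#'
#' @param mask logical array (2D or 3D).
#' @param voxel_size numeric, physical size of one voxel per axis (micrometre).
#' @return numeric array of distances in micrometre; `Inf` when `mask` is
#'   entirely `FALSE`.
#' @export
distance_transform <- function(mask, voxel_size) {
  stopifnot(is.logical(mask))
  d <- dim(mask)
  stopifnot(length(voxel_size) == length(d), all(voxel_size > 0))
  edt_cpp(mask, d, as.numeric(voxel_size))
}

# voxel index (1-based array indices, n x ndim) <-> linear index helpers
.vox_coords <- function(idx, dims) {
  nd <- length(dims)
  idx0 <- idx - 1L
  out <- matrix(0L, length(idx), nd)
  for (d in seq_len(nd)) {
    out[, d] <- idx0 %% dims[d] + 1L
    idx0 <- idx0 %/% dims[d]
  }
  out
}

# Deterministic sub-stream seed derivation (kept < 2^31).
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629) + 1L
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
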