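# Single-cell morphology features: soma size, skeleton endpoint/branch
# statistics, territorial (convex hull) volume and the ramification index
# (solidity: cell volume / hull volume; lower = more ramified).

#' Convex hull volume and ramification index of a cell mask
#'
#' The hull is taken over the corner points of the foreground voxels (each
#' voxel contributes its full physical extent), so a filled convex solid has
#' an index of 1 and the index is always in `(0, 1]`.
#'
#' @param mask logical array (2D or 3D).
#' @param voxel_size micrometre per voxel per axis.
#' @return list: `cell_volume` (um^3, or um^2 in 2D), `hull_volume`,
#'   `ramification_index = cell_volume / hull_volume`.
#' @export
hull_and_ramification <- function(mask, voxel_size) {
  stopifnot(is.logical(mask))
  d <- dim(mask)
  nd <- length(d)
  stopifnot(length(voxel_size) == nd)
  n_fg <- sum(mask)
  if (n_fg == 0) stop("empty mask")
  cell_volume <- n_fg * prod(voxel_size)
  idx <- which(mask)
  # boundary voxels suffice for the hull
  er <- .erode_face(mask)
  bidx <- which(mask & !er)
  if (length(bidx) == 0) bidx <- idx
  co <- .vox_coords(bidx, d)
  if (nd == 2L) {
    corners <- rbind(
      cbind(co[, 1] - 1, co[, 2] - 1), cbind(co[, 1], co[, 2] - 1),
      cbind(co[, 1] - 1, co[, 2]), cbind(co[, 1], co[, 2]))
    pts <- sweep(corners, 2, voxel_size[1:2], "*")
    pts <- unique(pts)
    if (nrow(pts) < 3) stop("degenerate geometry: fewer than 3 hull points")
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    if (nrow(hp) < 3) stop("degenerate geometry: collinear mask")
    x <- hp[, 1]; y <- hp[, 2]
    hull_volume <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  } else {
    offs <- as.matrix(expand.grid(0:1, 0:1, 0:1)) - 1
    corners <- do.call(rbind, lapply(seq_len(8), function(k) {
      sweep(co, 2, -offs[k, ])
    }))
    pts <- sweep(unique(corners), 2, voxel_size, "*")
    hull_volume <- convhull_volume_cpp(pts)
    if (hull_volume <= 0) stop("degenerate geometry: coplanar mask")
  }
  ri <- cell_volume / hull_volume
  list(cell_volume = cell_volume, hull_volume = hull_volume,
       ramification_index = min(ri, 1))
}

# face-connected erosion (voxels whose all face neighbours are foreground;
# out-of-volume counts as background)
.erode_face <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  shifted <- function(m, axis, by) {
    res <- array(FALSE, dim = d)
    n <- d[axis]
    if (abs(by) >= n) return(res)
    to <- lapply(d, seq_len)
    from <- to
    if (by > 0) { to[[axis]] <- 1:(n - by); from[[axis]] <- (1 + by):n }
    else { to[[axis]] <- (1 - by):n; from[[axis]] <- 1:(n + by) }
    res_sub <- do.call(`[`, c(list(m), from, list(drop = FALSE)))
    do.call(`[<-`, c(list(res), to, list(value = res_sub)))
  }
  out <- mask
  for (axis in seq_len(nd)) {
    out <- out & shifted(mask, axis, 1L) & shifted(mask, axis, -1L)
  }
  out
}

#' Compute the 8-feature morphology vector of one cell
#'
#' Features: soma area (um^2), number of endpoints, number of branch points,
#' maximum branch length (um), total branch length (um), cell volume (um^3;
#' area in 2D), convex hull volume (um^3; area in 2D) and ramification
#' index. Processes are measured on the skeleton outside the soma (skeleton
#' nodes inside the soma mask are contracted to one soma node).
#'
#' @param cell a `cell_record` from [extract_single_cells()] (or any list
#'   with `mask`, `soma_mask`, `soma_area_um2`).
#' @param voxel_size micrometre per voxel per axis.
#' @param prune_um spur-pruning length passed to [skeletonize_cell()].
#' @return named numeric vector of length 8.
#' @export
compute_features <- function(cell, voxel_size, prune_um = 1) {
  stopifnot(!is.null(cell$mask))
  sk <- skeletonize_cell(cell$mask, voxel_size, soma_mask = cell$soma_mask,
                         prune_um = prune_um)
  bs <- branch_stats(sk)
  hull <- hull_and_ramification(cell$mask, voxel_size)
  soma_area <- cell$soma_area_um2
  if (is.null(soma_area)) {
    info <- component_areas(array(as.integer(cell$soma_mask),
                                  dim = dim(cell$soma_mask)), voxel_size)
    soma_area <- info$area_um2[1]
  }
  c(soma_area_um2 = as.numeric(soma_area),
    n_endpoints = as.numeric(bs$n_endpoints),
    n_branchpoints = as.numeric(bs$n_branchpoints),
    max_branch_length_um = bs$max_branch_length,
    total_branch_length_um = bs$total_branch_length,
    cell_volume = hull$cell_volume,
    hull_volume = hull$hull_volume,
    ramification_index = hull$ramification_index)
}

#' Morphology feature table for a list of cells
#'
#' Touching cells (masks containing two or more somata) are excluded from
#' single-cell morphometrics.
#'
#' @param cells list of `cell_record`s from [extract_single_cells()].
#' @param voxel_size micrometre per voxel per axis.
#' @param prune_um spur-pruning length in um.
#' @return data frame, one row per retained cell, with `cell_id` plus the 8
#'   features.
#' @export
morphology_table <- function(cells, voxel_size, prune_um = 1) {
  cells <- Filter(function(cl) !isTRUE(cl$touching), cells)
  if (length(cells) == 0) {
    return(data.frame(cell_id = integer(),
                      soma_area_um2 = numeric(), n_endpoints = numeric(),
                      n_branchpoints = numeric(),
                      max_branch_length_um = numeric(),
                      total_branch_length_um = numeric(),
                      cell_volume = numeric(), hull_volume = numeric(),
                      ramification_index = numeric()))
  }
  feats <- t(vapply(cells, compute_features, numeric(8),
                    voxel_size = voxel_size, prune_um = prune_um))
  data.frame(cell_id = vapply(cells, function(cl) cl$cell_id, numeric(1)),
             feats)
}
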