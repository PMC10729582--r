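# Vascular-associated microglia (VAM): soma attached to a labeled vessel.

#' Classify vascular-associated microglia
#'
#' A cell is a VAM when the minimum Euclidean distance from any of its soma
#' voxels to the vessel mask is at most `attach_distance`. The default
#' attach distance is one voxel diagonal, i.e. direct contact up to
#' discretization.
#'
#' @param soma_labels integer array of soma labels (from [segment_somata()]).
#' @param vessel_mask logical array on the same grid.
#' @param voxel_size micrometre per voxel per axis.
#' @param attach_distance maximum soma-vessel gap in um; default
#'   `sqrt(sum(voxel_size^2))`.
#' @return data frame: `cell_id`, `gap_um` (minimum soma-vessel distance),
#'   `is_vam`.
#' @export
classify_vam <- function(soma_labels, vessel_mask, voxel_size,
                         attach_distance = NULL) {
  stopifnot(identical(dim(soma_labels), dim(vessel_mask)))
  if (is.null(attach_distance)) attach_distance <- sqrt(sum(voxel_size^2))
  ids <- sort(unique(soma_labels[soma_labels > 0]))
  if (length(ids) == 0) {
    return(data.frame(cell_id = integer(), gap_um = numeric(),
                      is_vam = logical()))
  }
  if (!any(vessel_mask)) {
    warning("empty vessel mask: no cell can be vessel-associated")
    return(data.frame(cell_id = ids, gap_um = Inf, is_vam = FALSE))
  }
  dt <- distance_transform(vessel_mask, voxel_size)
  gap <- vapply(ids, function(s) min(dt[soma_labels == s]), numeric(1))
  data.frame(cell_id = ids, gap_um = gap,
             is_vam = gap <= attach_distance)
}

#' Density standardized to one square millimetre
#'
#' @param count number of objects in the field of view.
#' @param fov_dim voxel grid dimensions of the FOV.
#' @param voxel_size micrometre per voxel per axis.
#' @return objects per mm^2 of xy footprint (the z extent is not used).
#' @export
density_per_mm2 <- function(count, fov_dim, voxel_size) {
  area_um2 <- fov_dim[1] * voxel_size[1] * fov_dim[2] * voxel_size[2]
  if (area_um2 <= 0) stop("FOV area must be positive")
  count / (area_um2 / 1e6)
}

#' Per-FOV VAM summary
#'
#' @param vam data frame from [classify_vam()].
#' @param fov_dim,voxel_size FOV geometry for the density standardization.
#' @return one-row data frame: `n_cells`, `n_vam`, `vam_frequency`,
#'   `microglia_per_mm2`, `vam_per_mm2`.
#' @export
vam_summary <- function(vam, fov_dim, voxel_size) {
  n <- nrow(vam)
  nv <- sum(vam$is_vam)
  data.frame(n_cells = n, n_vam = nv,
             vam_frequency = if (n > 0) nv / n else NA_real_,
             microglia_per_mm2 = density_per_mm2(n, fov_dim, voxel_size),
             vam_per_mm2 = density_per_mm2(nv, fov_dim, voxel_size))
}
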