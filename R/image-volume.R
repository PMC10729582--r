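# ImageVolume: a multi-channel 2D image or 3D z-stack with physical voxel
# size. Channels are stored as a named list of numeric arrays sharing one
# grid; intensities follow an 8-bit convention (0-255) so that fixed display
# thresholds are meaningful.

#' Create an image volume
#'
#' @param channels named list of numeric arrays (all the same dimension),
#'   e.g. `list(iba1 = ..., vessel = ..., igg = ...)`.
#' @param voxel_size numeric vector, micrometre per voxel along each axis
#'   (length 2 for a single plane, 3 for a z-stack).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(channels, voxel_size) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- dim(channels[[1]])
  if (is.null(dims)) stop("channels must be arrays with a dim attribute")
  for (ch in channels) {
    if (!identical(dim(ch), dims)) stop("all channels must share one grid")
    if (!all(is.finite(ch))) stop("channel intensities must be finite")
  }
  nd <- length(dims)
  if (!nd %in% c(2L, 3L)) stop("channels must be 2D or 3D arrays")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != nd || any(voxel_size <= 0))
    stop("voxel_size must be strictly positive and match dimensionality")
  structure(list(channels = channels, voxel_size = voxel_size, dim = dims),
            class = "image_volume")
}

#' @export
#' @method print image_volume
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(x$dim, collapse = " x "), " voxels, ",
      paste(signif(x$voxel_size, 3), collapse = " x "), " um/voxel\n",
      "channels: ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# xy pixel area in um^2 (used by all area-based filters)
pixel_area_um2 <- function(vol_or_voxel) {
  vs <- if (inherits(vol_or_voxel, "image_volume")) vol_or_voxel$voxel_size else vol_or_voxel
  vs[1] * vs[2]
}

#' Write an image volume as TIFF plus a JSON sidecar
#'
#' One multi-plane TIFF per field of view: planes are ordered channel-fastest
#' within each z-slice; the sidecar (`<file>.json`) records shape, voxel size
#' and channel names so that [read_fov_tiff()] restores the volume exactly.
#' Intensities are stored as 8-bit samples (values clipped to 0-255).
#'
#' @param vol an [image_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_fov_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  nz <- if (length(vol$dim) == 3) vol$dim[3] else 1L
  planes <- list()
  for (z in seq_len(nz)) {
    for (ch in names(vol$channels)) {
      a <- vol$channels[[ch]]
      pl <- if (length(vol$dim) == 3) a[, , z] else a
      pl <- pmin(pmax(round(pl), 0), 255) / 255
      planes[[length(planes) + 1L]] <- pl
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 8L)
  meta <- list(shape = as.integer(vol$dim), voxel_size_um = vol$voxel_size,
               channels = names(vol$channels), plane_order = "z-major, channel-fastest")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a field of view written by [write_fov_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return an [image_volume()].
#' @export
read_fov_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  shape <- as.integer(meta$shape)
  nz <- if (length(shape) == 3) shape[3] else 1L
  nch <- length(meta$channels)
  stopifnot(length(planes) == nz * nch)
  channels <- lapply(seq_len(nch), function(ci) {
    a <- array(0, dim = shape)
    for (z in seq_len(nz)) {
      pl <- round(planes[[(z - 1L) * nch + ci]] * 255)
      if (length(shape) == 3) a[, , z] <- pl else a[, ] <- pl
    }
    a
  })
  names(channels) <- meta$channels
  image_volume(channels, meta$voxel_size_um)
}
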