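# Synthetic confocal field-of-view generator: configuration and shared
# rendering helpers. FOVs are generated in micrometre coordinates and
# rasterized with the per-axis voxel size, so the same generative model
# serves both acquisition settings (1.25 x 1.25 x 1 um counting stacks and
# 0.16 x 0.16 x 0.3 um single-cell stacks) as well as 2D planes.

#' Configuration of one synthetic field of view
#'
#' Defaults emulate the low-magnification counting acquisition: a
#' 160 x 160 x 24 um stack at 1.25 x 1.25 x 1 um voxels containing a small
#' tubular vessel network, branched microglia with bright somata (a fraction
#' planted in contact with vessels) and perivascular leakage blobs, under
#' Gaussian read noise plus Poisson shot noise on an 8-bit scale.
#'
#' @param shape voxels per axis (length 2 or 3; a third entry of 1 is a 2D
#'   plane).
#' @param voxel_size micrometre per voxel per axis.
#' @param n_vessels number of vessels.
#' @param vessel_radius_range vessel radius range in um.
#' @param n_cells number of microglia.
#' @param soma_radius_range soma semi-axis range in um.
#' @param branches_per_cell integer range of primary branches per cell.
#' @param branch_length_range primary branch length range in um.
#' @param process_radius_range branch calibre range in um.
#' @param branch_split_prob probability that a primary branch bifurcates at
#'   its end into two shorter children.
#' @param vam_fraction fraction of cells planted with the soma touching a
#'   vessel.
#' @param leakage_fraction target fraction of the FOV above the fixed IgG
#'   display threshold.
#' @param igg_threshold the display threshold the leakage target refers to
#'   (8-bit scale); default 25.
#' @param noise list with `sigma` (Gaussian read-noise SD, intensity units)
#'   and `poisson` (logical, shot noise).
#' @param background additive background intensity per channel.
#' @param cell_clearance_um minimum gap between a non-planted soma and the
#'   vessel surface (keeps planted labels unambiguous).
#' @param seed integer master seed; all per-stage streams derive from it.
#' @return a validated `fov_config`.
#' @export
fov_config <- function(shape = c(128, 128, 24),
                       voxel_size = c(1.25, 1.25, 1),
                       n_vessels = 4,
                       vessel_radius_range = c(2, 4),
                       n_cells = 12,
                       soma_radius_range = c(4.8, 6),
                       branches_per_cell = c(3, 6),
                       branch_length_range = c(8, 25),
                       process_radius_range = c(0.3, 0.6),
                       branch_split_prob = 0.35,
                       vam_fraction = 0.3,
                       leakage_fraction = 0.05,
                       igg_threshold = 25,
                       noise = list(sigma = 5, poisson = TRUE),
                       background = 8,
                       cell_clearance_um = 5,
                       seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(shape) != 3L || any(shape <= 0))
    stop("configuration error: shape must be strictly positive")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 2L) voxel_size <- c(voxel_size, 1)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("configuration error: voxel_size must be strictly positive")
  if (n_vessels < 0 || n_cells < 0) stop("counts must be >= 0")
  if (vam_fraction < 0 || vam_fraction > 1)
    stop("vam_fraction must lie in [0, 1]")
  if (leakage_fraction < 0 || leakage_fraction > 1)
    stop("leakage_fraction must lie in [0, 1]")
  if (is.null(noise$sigma) || noise$sigma < 0)
    stop("noise sigma must be >= 0")
  rng2 <- function(r) { r <- as.numeric(r); if (length(r) == 1) c(r, r) else r }
  cfg <- list(shape = shape, voxel_size = voxel_size,
              n_vessels = as.integer(n_vessels),
              vessel_radius_range = rng2(vessel_radius_range),
              n_cells = as.integer(n_cells),
              soma_radius_range = rng2(soma_radius_range),
              branches_per_cell = as.integer(rng2(branches_per_cell)),
              branch_length_range = rng2(branch_length_range),
              process_radius_range = rng2(process_radius_range),
              branch_split_prob = branch_split_prob,
              vam_fraction = vam_fraction,
              leakage_fraction = leakage_fraction,
              igg_threshold = igg_threshold,
              noise = list(sigma = noise$sigma,
                           poisson = isTRUE(noise$poisson)),
              background = background,
              cell_clearance_um = cell_clearance_um,
              seed = as.integer(seed))
  structure(cfg, class = "fov_config")
}

#' Single-cell morphology acquisition preset
#'
#' High-resolution stack for one cell, matching the single-cell acquisition
#' voxel size (0.16 x 0.16 x 0.3 um); no vessels or leakage by default.
#'
#' @param ... overrides passed to [fov_config()].
#' @export
fov_config_morphology <- function(...) {
  defaults <- list(shape = c(320, 320, 110),
                   voxel_size = c(0.16, 0.16, 0.3),
                   n_vessels = 0, n_cells = 1,
                   soma_radius_range = c(3, 4.5),
                   branches_per_cell = c(3, 6),
                   branch_length_range = c(6, 16),
                   process_radius_range = c(0.4, 0.6),
                   leakage_fraction = 0, vam_fraction = 0,
                   noise = list(sigma = 3, poisson = TRUE))
  do.call(fov_config, modifyList(defaults, list(...)))
}

# --- rendering helpers (micrometre coordinates, column-major arrays) ------

.fov_extent_um <- function(config) config$shape * config$voxel_size

.is2d <- function(config) config$shape[3] == 1L

# voxel centres along each axis in um
.axis_centers <- function(config) {
  lapply(1:3, function(a) (seq_len(config$shape[a]) - 0.5) * config$voxel_size[a])
}

# Patch for a soft-edged ball: index ranges plus intensity and hard-mask
# patches; callers merge with pmax / `|` so big arrays stay in place.
# `pv` caps the intensity for sub-voxel structures (partial-volume dimming
# of thin processes at coarse voxels).
.ball_patch <- function(config, center, radius, intensity, pv = 1) {
  sh <- config$shape; vs <- config$voxel_size
  lo <- pmax(floor((center - radius) / vs - 1), 0) + 1
  hi <- pmin(ceiling((center + radius) / vs + 1), sh)
  if (any(lo > hi)) return(NULL)
  ax <- lapply(1:3, function(a) (seq(lo[a], hi[a]) - 0.5) * vs[a])
  d <- sqrt(outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
                  (ax[[3]] - center[3])^2, "+"))
  w <- mean(vs[1:2])
  cover <- pmin(pmax((radius - d) / w + 0.5, 0), 1)
  list(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3],
       img = intensity * pv * cover, mask = d <= radius)
}

# Patch for an ellipsoid (semi-axes `axes` um).
.ellipsoid_patch <- function(config, center, axes, intensity) {
  sh <- config$shape; vs <- config$voxel_size
  r <- max(axes)
  lo <- pmax(floor((center - r) / vs - 1), 0) + 1
  hi <- pmin(ceiling((center + r) / vs + 1), sh)
  if (any(lo > hi)) return(NULL)
  ax <- lapply(1:3, function(a) (seq(lo[a], hi[a]) - 0.5) * vs[a])
  q <- outer(outer(((ax[[1]] - center[1]) / axes[1])^2,
                   ((ax[[2]] - center[2]) / axes[2])^2, "+"),
             ((ax[[3]] - center[3]) / axes[3])^2, "+")
  w <- mean(vs[1:2]) / mean(axes)
  cover <- pmin(pmax((1 - sqrt(q)) / w + 0.5, 0), 1)
  list(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3],
       img = intensity * cover, mask = q <= 1)
}

.unit <- function(v) v / sqrt(sum(v^2))

# random unit vector (confined to the xy plane when two_d)
.rand_dir <- function(two_d) {
  repeat {
    v <- rnorm(3)
    if (two_d) v[3] <- 0
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Add acquisition noise to a channel
#'
#' Optional Poisson shot noise (the clean intensity is used as the photon
#' expectation) followed by additive Gaussian read noise; the result is
#' rounded and clipped to the 8-bit range.
#'
#' @param channel numeric array of clean intensities.
#' @param sigma Gaussian read-noise standard deviation (>= 0).
#' @param poisson logical, apply shot noise.
#' @param seed integer seed.
#' @param dtype_max intensity ceiling; default 255.
#' @return noisy channel, same shape.
#' @export
add_noise <- function(channel, sigma = 5, poisson = TRUE, seed = 1L,
                      dtype_max = 255) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  d <- dim(channel)
  if (sigma == 0 && !poisson) return(channel)
  out <- .with_seed(seed, {
    v <- as.numeric(channel)
    if (poisson) v <- rpois(length(v), pmax(v, 0))
    if (sigma > 0) v <- v + rnorm(length(v), 0, sigma)
    v
  })
  out <- pmin(pmax(round(out), 0), dtype_max)
  dim(out) <- d
  out
}
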