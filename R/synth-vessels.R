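# Vessel network rendering: smooth random centerlines rasterized as tubes.

#' Generate the vessel channel of a synthetic FOV
#'
#' Each vessel is a smooth random-walk centerline entering at a random face
#' and traversing the FOV. The tube is rendered from the exact Euclidean
#' distance between voxel centres and the centerline polyline (capsule
#' distance per segment, in um), giving a sub-voxel-accurate boundary: the
#' mask is `distance <= radius` and the intensity is a filled profile with
#' a one-voxel soft edge (point-spread-like rolloff).
#'
#' @param config a [fov_config()].
#' @return list: `channel` (clean intensity array, no background/noise),
#'   `truth` (list with `mask`, `centerlines` (list of um-coordinate
#'   polylines), `radii`).
#' @export
generate_vessels <- function(config) {
  stopifnot(inherits(config, "fov_config"))
  sh <- config$shape
  ext <- .fov_extent_um(config)
  two_d <- .is2d(config)
  channel <- array(0, dim = sh)
  mask <- array(FALSE, dim = sh)
  centerlines <- list()
  radii <- numeric()
  if (config$n_vessels == 0) {
    return(list(channel = channel,
                truth = list(mask = mask, centerlines = centerlines,
                             radii = radii)))
  }
  w <- mean(config$voxel_size[1:2])
  .with_seed(.derive_seed(config$seed, 11L), {
    step <- max(1, 2 * min(config$voxel_size[if (two_d) 1:2 else 1:3]))
    for (v in seq_len(config$n_vessels)) {
      r <- runif(1, config$vessel_radius_range[1], config$vessel_radius_range[2])
      # entry point on a random face, aimed at the central region so the
      # tube traverses the FOV instead of clipping a corner
      axis <- if (two_d) sample(1:2, 1) else sample(1:3, 1)
      side <- sample(c(0, 1), 1)
      p <- runif(3) * ext
      p[axis] <- side * ext[axis]
      if (two_d) p[3] <- ext[3] / 2
      target <- ext * runif(3, 0.3, 0.7)
      if (two_d) target[3] <- ext[3] / 2
      dir <- .unit(target - p)
      pts <- matrix(p, ncol = 3)
      max_steps <- ceiling(3 * sum(ext) / step)
      for (k in seq_len(max_steps)) {
        wiggle <- rnorm(3, 0, 0.08)
        if (two_d) wiggle[3] <- 0
        dir <- .unit(dir + wiggle)
        p <- p + dir * step
        if (any(p < -r) || any(p > ext + r)) break
        pts <- rbind(pts, p)
      }
      centerlines[[v]] <- pts
      radii[v] <- r
      # exact distance to the polyline within a capsule around each segment
      for (k in seq_len(nrow(pts) - 1)) {
        cp <- .capsule_patch(config, pts[k, ], pts[k + 1, ], r + 1.5 * w)
        if (is.null(cp)) next
        d <- cp$dist
        mask[cp$ix, cp$iy, cp$iz] <- mask[cp$ix, cp$iy, cp$iz] | (d <= r)
        prof <- pmin(pmax((r - d) / w + 0.5, 0), 1)
        channel[cp$ix, cp$iy, cp$iz] <- pmax(channel[cp$ix, cp$iy, cp$iz],
                                             200 * prof)
      }
    }
  })
  list(channel = channel,
       truth = list(mask = mask, centerlines = centerlines, radii = radii))
}

# distance from voxel centres to the segment a-b within a bounding box of
# radius `rmax` around the segment
.capsule_patch <- function(config, a, b, rmax) {
  sh <- config$shape; vs <- config$voxel_size
  lo <- pmax(floor((pmin(a, b) - rmax) / vs - 1), 0) + 1
  hi <- pmin(ceiling((pmax(a, b) + rmax) / vs + 1), sh)
  if (any(lo > hi)) return(NULL)
  ax <- lapply(1:3, function(i) (seq(lo[i], hi[i]) - 0.5) * vs[i])
  n1 <- length(ax[[1]]); n2 <- length(ax[[2]]); n3 <- length(ax[[3]])
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) { ab <- c(0, 0, 0); len2 <- 1 }
  # t = clamp(((p - a) . ab) / |ab|^2, 0, 1), distance to a + t ab
  tx <- outer(outer((ax[[1]] - a[1]) * ab[1], (ax[[2]] - a[2]) * ab[2], "+"),
              (ax[[3]] - a[3]) * ab[3], "+") / len2
  tt <- pmin(pmax(tx, 0), 1)
  dx <- outer(outer(ax[[1]] - a[1], numeric(n2) , "+"), numeric(n3), "+") - tt * ab[1]
  dy <- outer(outer(numeric(n1), ax[[2]] - a[2], "+"), numeric(n3), "+") - tt * ab[2]
  dz <- outer(outer(numeric(n1), numeric(n2), "+"), ax[[3]] - a[3], "+") - tt * ab[3]
  list(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3],
       dist = sqrt(dx * dx + dy * dy + dz * dz))
}
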