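# Microglia rendering: ellipsoidal somata plus random trees of tapering
# branches, generated as explicit polylines first (ground truth lives on
# the tree) and rasterized second.

# one random branch polyline of exact length `len`, reflected off the FOV
# margins so the tree stays inside the volume
.branch_polyline <- function(start, dir, len, ext, margin, two_d,
                             step = 0.5, curvature_sd = 0.06) {
  n_steps <- max(2, ceiling(len / step))
  ss <- len / n_steps
  pts <- matrix(NA_real_, n_steps + 1, 3)
  pts[1, ] <- start
  p <- start
  for (k in seq_len(n_steps)) {
    wiggle <- rnorm(3, 0, curvature_sd)
    if (two_d) wiggle[3] <- 0
    dir <- .unit(dir + wiggle)
    nxt <- p + dir * ss
    for (a in if (two_d) 1:2 else 1:3) {
      if (nxt[a] < margin[a] || nxt[a] > ext[a] - margin[a]) {
        dir[a] <- -dir[a]
        nxt <- p + dir * ss
      }
    }
    p <- nxt
    pts[k + 1, ] <- p
  }
  pts
}

# directions with pairwise angular separation (best effort within `tries`)
.separated_dirs <- function(n, two_d, min_angle = 50, tries = 400) {
  dirs <- list()
  cosmax <- cos(min_angle * pi / 180)
  for (i in seq_len(n)) {
    best <- NULL; best_sep <- -Inf
    for (t in seq_len(tries)) {
      cand <- .rand_dir(two_d)
      sep <- if (length(dirs) == 0) 1 else
        -max(vapply(dirs, function(d0) sum(d0 * cand), numeric(1)))
      if (sep > best_sep) { best_sep <- sep; best <- cand }
      if (length(dirs) == 0 || -best_sep <= cosmax) break
    }
    dirs[[i]] <- best
  }
  dirs
}

# rotate `dir` by `angle_deg` about a random perpendicular axis
.tilt_dir <- function(dir, angle_deg, two_d) {
  th <- angle_deg * pi / 180
  if (two_d) {
    s <- sample(c(-1, 1), 1)
    R <- matrix(c(cos(s * th), sin(s * th), -sin(s * th), cos(s * th)), 2, 2)
    c(R %*% dir[1:2], 0)
  } else {
    perp <- .unit(pracma_cross(dir, .rand_dir(FALSE)))
    .unit(dir * cos(th) + perp * sin(th))
  }
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# TRUE when every pair of branch polylines keeps at least `clearance` um
# between sample points, ignoring points near the soma and near shared
# junctions: skeleton-based endpoint/branch counts are only exact for such
# trees (merging processes fuse in the rendered mask).
.branches_separated <- function(branch_pts, branch_anchor, soma_center,
                                soma_excl, clearance) {
  nb <- length(branch_pts)
  if (nb < 2) return(TRUE)
  trimmed <- lapply(seq_len(nb), function(i) {
    p <- branch_pts[[i]]
    keep <- sqrt(colSums((t(p) - soma_center)^2)) > soma_excl
    for (j in seq_len(nrow(branch_anchor[[i]]))) {
      keep <- keep & sqrt(colSums((t(p) - branch_anchor[[i]][j, ])^2)) > 2
    }
    p[keep, , drop = FALSE]
  })
  for (i in seq_len(nb - 1)) {
    pi_ <- trimmed[[i]]
    if (nrow(pi_) == 0) next
    for (j in (i + 1):nb) {
      pj <- trimmed[[j]]
      if (nrow(pj) == 0) next
      d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") -
        2 * pi_ %*% t(pj)
      if (sqrt(max(min(d2), 0)) < clearance) return(FALSE)
    }
  }
  TRUE
}

#' Generate the microglia channel of a synthetic FOV
#'
#' Renders each cell as a bright ellipsoidal soma plus a random tree of
#' tapering branches. A `vam_fraction` subset of cells is planted with the
#' soma overlapping the vessel mask; all other somata keep a clearance of at
#' least `cell_clearance_um` from the vessel surface. Branch trees are
#' generated as explicit polylines, so per-branch lengths and endpoint
#' counts are defined on the tree, not re-measured from voxels.
#'
#' @param config a [fov_config()].
#' @param vessel_truth the `truth` element of [generate_vessels()]; required
#'   when `vam_fraction > 0`.
#' @param fov_id identifier used in error messages.
#' @return list: `channel` (clean intensities, no background/noise), `truth`
#'   (list with `cells` data frame, per-cell `masks` and `soma_masks`,
#'   `branch_lengths` list).
#' @export
generate_microglia <- function(config, vessel_truth = NULL, fov_id = "fov") {
  stopifnot(inherits(config, "fov_config"))
  sh <- config$shape
  ext <- .fov_extent_um(config)
  two_d <- .is2d(config)
  channel <- array(0, dim = sh)
  n <- config$n_cells
  empty_truth <- list(cells = data.frame(), masks = list(),
                      soma_masks = list(), branch_lengths = list())
  if (n == 0) return(list(channel = channel, truth = empty_truth))
  if (config$vam_fraction > 0 &&
      (is.null(vessel_truth) || !any(vessel_truth$mask)))
    stop("vessel truth required to plant vessel-associated cells")
  vdist <- if (!is.null(vessel_truth) && any(vessel_truth$mask)) {
    distance_transform(vessel_truth$mask, config$voxel_size)
  } else NULL
  vidx <- if (!is.null(vdist)) which(vessel_truth$mask) else integer()

  rows <- list(); masks <- list(); soma_masks <- list(); blens <- list()
  .with_seed(.derive_seed(config$seed, 23L), {
    # per-cell Bernoulli planting: FOV-level VAM frequencies then carry the
    # sampling variability real fields of view show
    vam_flags <- runif(n) < config$vam_fraction
    centers <- matrix(NA_real_, 0, 3)
    soma_rs <- numeric()
    for (ci in seq_len(n)) {
      r <- runif(1, config$soma_radius_range[1], config$soma_radius_range[2])
      is_vam <- vam_flags[ci]
      placed <- FALSE
      for (try in seq_len(1500)) {
        # generous spacing first; relax the extra margin (never the
        # non-overlap core) when the FOV is crowded
        gap_extra <- if (try <= 500) 6 else if (try <= 1000) 4 else 3
        if (is_vam) {
          vi <- vidx[sample.int(length(vidx), 1)]
          vc <- (.vox_coords(vi, sh)[1, ] - 0.5) * config$voxel_size
          cand <- vc + .rand_dir(two_d) * (0.6 * r)
          cand <- pmin(pmax(cand, r), ext - r)
          if (two_d) cand[3] <- ext[3] / 2
        } else {
          cand <- runif(3) * (ext - 2 * (r + 1)) + r + 1
          if (two_d) cand[3] <- ext[3] / 2
          if (!is.null(vdist)) {
            vi2 <- pmin(pmax(ceiling(cand / config$voxel_size), 1), sh)
            gap <- vdist[vi2[1], vi2[2], vi2[3]]
            if (gap < r + config$cell_clearance_um) next
          }
        }
        if (nrow(centers) > 0) {
          dd <- sqrt(rowSums(sweep(centers, 2, cand)^2))
          if (any(dd < soma_rs + r + gap_extra)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("placement error in ", fov_id, ": cannot place cell ", ci,
             " without overlap")
      centers <- rbind(centers, cand)
      soma_rs <- c(soma_rs, r)
    }
    # render each cell
    for (ci in seq_len(n)) {
      center <- centers[ci, ]
      r <- soma_rs[ci]
      axes <- r * runif(3, 0.95, 1.1)
      if (two_d) axes[3] <- ext[3] # fills the single plane
      soma_mask <- array(FALSE, dim = sh)
      cell_mask <- array(FALSE, dim = sh)
      ep <- .ellipsoid_patch(config, center, axes, 200)
      channel[ep$ix, ep$iy, ep$iz] <- pmax(channel[ep$ix, ep$iy, ep$iz], ep$img)
      soma_mask[ep$ix, ep$iy, ep$iz] <- ep$mask
      cell_mask[ep$ix, ep$iy, ep$iz] <- ep$mask

      nb <- if (config$branches_per_cell[2] > 0) {
        sample(config$branches_per_cell[1]:config$branches_per_cell[2], 1)
      } else 0L
      lens <- numeric()
      n_leaves <- 0L
      branch_pts <- list()   # sampled polylines for the separation check
      branch_anchor <- list() # shared-junction point to exclude per branch
      if (nb > 0) {
        dirs <- .separated_dirs(nb, two_d)
        margin <- rep(1, 3)
        if (two_d) margin[3] <- 0
        r0 <- runif(1, config$process_radius_range[1],
                    config$process_radius_range[2])
        for (b in seq_len(nb)) {
          dir <- dirs[[b]]
          # start on the soma surface along dir
          sr <- 1 / sqrt(sum((dir / axes)^2))
          start <- center + dir * (0.9 * sr)
          len <- runif(1, config$branch_length_range[1],
                       config$branch_length_range[2])
          pts <- .branch_polyline(start, dir, len, ext, margin, two_d)
          res <- .render_branch(channel, cell_mask, config, pts, r0, 0.45 * r0)
          channel <- res$img; cell_mask <- res$mask
          lens <- c(lens, len)
          branch_pts[[length(branch_pts) + 1L]] <- pts
          branch_anchor[[length(branch_anchor) + 1L]] <- rbind(center)
          split <- runif(1) < config$branch_split_prob
          if (split) {
            tip <- pts[nrow(pts), ]
            pidx <- length(branch_anchor)
            branch_anchor[[pidx]] <- rbind(branch_anchor[[pidx]], tip)
            tdir <- .unit(pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
            for (s in 1:2) {
              cdir <- .tilt_dir(tdir, runif(1, 25, 50), two_d)
              clen <- len * runif(1, 0.4, 0.7)
              cpts <- .branch_polyline(tip, cdir, clen, ext, margin, two_d)
              res <- .render_branch(channel, cell_mask, config, cpts,
                                    0.6 * r0, 0.4 * r0)
              channel <- res$img; cell_mask <- res$mask
              lens <- c(lens, clen)
              branch_pts[[length(branch_pts) + 1L]] <- cpts
              branch_anchor[[length(branch_anchor) + 1L]] <- rbind(center, tip)
              n_leaves <- n_leaves + 1L
            }
          } else {
            n_leaves <- n_leaves + 1L
          }
        }
      }
      well_sep <- .branches_separated(
        branch_pts, branch_anchor, soma_center = center,
        soma_excl = max(axes) + 1,
        clearance = 2 * config$process_radius_range[2] +
          2 * max(config$voxel_size))
      soma_info <- component_areas(array(as.integer(soma_mask), dim = sh),
                                   config$voxel_size)
      n_end_truth <- if (nb == 0) 0L else n_leaves + (if (nb == 1) 1L else 0L)
      rows[[ci]] <- data.frame(
        cell_id = ci,
        x_um = center[1], y_um = center[2], z_um = center[3],
        soma_area_um2 = soma_info$area_um2[1],
        n_primary_branches = nb,
        n_branches = length(lens),
        n_endpoints = n_end_truth,
        max_branch_length_um = if (length(lens)) max(lens) else 0,
        total_branch_length_um = sum(lens),
        well_separated = well_sep,
        is_vam = vam_flags[ci])
      masks[[ci]] <- cell_mask
      soma_masks[[ci]] <- soma_mask
      blens[[ci]] <- lens
    }
  })
  truth <- list(cells = do.call(rbind, rows), masks = masks,
                soma_masks = soma_masks, branch_lengths = blens)
  list(channel = channel, truth = truth)
}

# stamp a tapering branch polyline (radius r_from at the root to r_to at
# the tip); partial-volume dimming applies at coarse voxels
.render_branch <- function(img, mask, config, pts, r_from, r_to) {
  nseg <- nrow(pts)
  vs <- config$voxel_size
  px <- vs[1] * vs[2]
  # stamp at sub-voxel spacing along the polyline
  fine_step <- 0.6 * min(vs)
  for (k in seq_len(nseg - 1)) {
    a <- pts[k, ]; b <- pts[k + 1, ]
    seg <- sqrt(sum((b - a)^2))
    ns <- max(1, ceiling(seg / fine_step))
    for (s in 0:ns) {
      f_seg <- s / ns
      f_all <- (k - 1 + f_seg) / (nseg - 1)
      p <- a + (b - a) * f_seg
      r <- r_from + (r_to - r_from) * f_all
      pv <- min(1, pi * r^2 / px)
      inten <- 150 - 60 * f_all
      bp <- .ball_patch(config, p, max(r, 0.6 * max(vs)), inten, pv)
      if (is.null(bp)) next
      img[bp$ix, bp$iy, bp$iz] <- pmax(img[bp$ix, bp$iy, bp$iz], bp$img)
      mask[bp$ix, bp$iy, bp$iz] <- mask[bp$ix, bp$iy, bp$iz] | bp$mask
    }
  }
  list(img = img, mask = mask)
}
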