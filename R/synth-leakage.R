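# Perivascular leakage rendering: diffuse blobs of plasma-protein signal
# placed just outside the vessel wall until the above-threshold fraction of
# the FOV reaches the target.

#' Generate the IgG leakage channel of a synthetic FOV
#'
#' Stamps Gaussian-profile perivascular blobs (peak intensity well above the
#' fixed display threshold) until the fraction of voxels above
#' `config$igg_threshold` reaches `config$leakage_fraction`; the achieved
#' fraction is recomputed from the clean channel and recorded as truth. When
#' the target cannot be reached with the available perivascular space a
#' warning is raised and the achieved fraction recorded.
#'
#' @param config a [fov_config()].
#' @param vessel_truth the `truth` element of [generate_vessels()]; blobs
#'   are placed anywhere when no vessel exists.
#' @param baseline additive background the composed channel will carry;
#'   the above-threshold fraction is evaluated on `channel + baseline` so
#'   the recorded truth matches the assembled field of view.
#' @return list: `channel` (clean, no background/noise),
#'   `true_leakage_fraction`.
#' @export
generate_leakage <- function(config, vessel_truth = NULL,
                             baseline = 0.8 * config$background) {
  stopifnot(inherits(config, "fov_config"))
  sh <- config$shape
  ext <- .fov_extent_um(config)
  two_d <- .is2d(config)
  channel <- array(0, dim = sh)
  target <- config$leakage_fraction
  thr <- config$igg_threshold
  if (target == 0)
    return(list(channel = channel, true_leakage_fraction = 0))
  vidx <- if (!is.null(vessel_truth) && any(vessel_truth$mask))
    which(vessel_truth$mask) else integer()
  achieved <- 0
  .with_seed(.derive_seed(config$seed, 37L), {
    max_blobs <- 20000L
    stall <- 0L
    for (b in seq_len(max_blobs)) {
      if (length(vidx)) {
        vi <- vidx[sample.int(length(vidx), 1)]
        vc <- (.vox_coords(vi, sh)[1, ] - 0.5) * config$voxel_size
        center <- vc + .rand_dir(two_d) * runif(1, 1, 5)
      } else {
        center <- runif(3) * ext
      }
      if (two_d) center[3] <- ext[3] / 2
      center <- pmin(pmax(center, 0), ext)
      sigma <- runif(1, 2.5, 6)
      peak <- runif(1, 80, 160)
      before <- achieved
      channel <- .stamp_gaussian_blob(channel, config, center, sigma, peak)
      achieved <- mean(channel + baseline > thr)
      if (achieved >= target) break
      stall <- if (achieved - before < 1e-7) stall + 1L else 0L
      if (stall >= 500L) break
    }
  })
  if (achieved < target - 0.02)
    warning(sprintf("leakage target %.3f not achievable; achieved %.3f",
                    target, achieved))
  list(channel = channel, true_leakage_fraction = achieved)
}

.stamp_gaussian_blob <- function(img, config, center, sigma, peak) {
  sh <- config$shape; vs <- config$voxel_size
  r <- 3 * sigma
  lo <- pmax(floor((center - r) / vs - 1), 0) + 1
  hi <- pmin(ceiling((center + r) / vs + 1), sh)
  if (any(lo > hi)) return(img)
  ax <- lapply(1:3, function(a) (seq(lo[a], hi[a]) - 0.5) * vs[a])
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
              (ax[[3]] - center[3])^2, "+")
  sub <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  blob <- peak * exp(-d2 / (2 * sigma^2))
  dim(blob) <- dim(sub)
  img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(sub, blob)
  img
}

#' Feature-space draws from four microglial morphology archetypes
#'
#' Emits 8-feature vectors from four generative regimes with distinct soma
#' size, branching and ramification-index distributions: `amoeboid` (large
#' soma, few short processes, high RI), `hypertrophic` (large soma, thick
#' mid-length processes), `ramified` (small soma, many long processes, low
#' RI) and `transitional` (intermediate). Used to validate the clustering
#' stage with known labels.
#'
#' @param n_per cells per archetype.
#' @param seed integer seed.
#' @return data frame with `archetype` plus the 8 morphology features.
#' @export
archetype_features <- function(n_per = 30, seed = 1L) {
  regimes <- list(
    amoeboid      = list(soma = c(110, 10), ends = c(2, 1),  bp = c(1, 1),
                         maxlen = c(6, 1.5),  total = c(12, 3),
                         vol = c(900, 90),  ri = c(0.85, 0.04)),
    hypertrophic  = list(soma = c(95, 9),  ends = c(8, 2),  bp = c(5, 1.5),
                         maxlen = c(18, 3),  total = c(80, 12),
                         vol = c(1500, 150), ri = c(0.45, 0.05)),
    ramified      = list(soma = c(55, 6),  ends = c(18, 3), bp = c(12, 2.5),
                         maxlen = c(32, 4),  total = c(260, 30),
                         vol = c(1200, 120), ri = c(0.12, 0.03)),
    transitional  = list(soma = c(75, 7),  ends = c(12, 2), bp = c(8, 2),
                         maxlen = c(25, 3),  total = c(160, 20),
                         vol = c(1100, 110), ri = c(0.28, 0.04)))
  .with_seed(seed, {
    out <- lapply(names(regimes), function(a) {
      g <- regimes[[a]]
      data.frame(
        archetype = a,
        soma_area_um2 = pmax(rnorm(n_per, g$soma[1], g$soma[2]), 20),
        n_endpoints = pmax(round(rnorm(n_per, g$ends[1], g$ends[2])), 0),
        n_branchpoints = pmax(round(rnorm(n_per, g$bp[1], g$bp[2])), 0),
        max_branch_length_um = pmax(rnorm(n_per, g$maxlen[1], g$maxlen[2]), 1),
        total_branch_length_um = pmax(rnorm(n_per, g$total[1], g$total[2]), 2),
        cell_volume = pmax(rnorm(n_per, g$vol[1], g$vol[2]), 100),
        hull_volume = NA_real_,
        ramification_index = pmin(pmax(rnorm(n_per, g$ri[1], g$ri[2]), 0.02), 1))
    })
    out <- do.call(rbind, out)
    out$hull_volume <- out$cell_volume / out$ramification_index
    out
  })
}
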