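# Soma detection, single-cell mask extraction and IgG leakage quantification.
# All size filters use strict inequalities and physical units.

#' Segmentation parameters for the cell and leakage channels
#'
#' @param soma_min_area minimum soma area in um^2 (strictly greater than);
#'   default 60.
#' @param threshold_method automatic global threshold for the cell channel:
#'   `"otsu"` (rodent 3D mode) or `"triangle"` (human 2D mode).
#' @param single_cell_min_size minimum single-cell component size in pixels,
#'   applied in the 2D human mode (strictly greater than); default 2000.
#' @param igg_threshold fixed intensity threshold for the leakage channel
#'   (strictly greater than); default 25 on the 8-bit scale.
#' @param igg_min_area minimum leakage component area in um^2 (strictly
#'   greater than); default 5.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(soma_min_area = 60,
                                threshold_method = c("otsu", "triangle"),
                                single_cell_min_size = 2000,
                                igg_threshold = 25,
                                igg_min_area = 5) {
  threshold_method <- match.arg(threshold_method)
  if (soma_min_area <= 0 || igg_min_area <= 0 || single_cell_min_size <= 0)
    stop("size filters must be positive")
  if (igg_threshold < 0 || igg_threshold > 255)
    stop("igg_threshold must lie in the 8-bit range")
  structure(list(soma_min_area = soma_min_area,
                 threshold_method = threshold_method,
                 single_cell_min_size = single_cell_min_size,
                 igg_threshold = igg_threshold,
                 igg_min_area = igg_min_area),
            class = "segmentation_params")
}

#' Automatic global threshold of an intensity histogram
#'
#' `"otsu"` maximizes between-class variance over a 256-bin histogram;
#' `"triangle"` takes the bin with maximal distance from the line joining the
#' histogram peak to the far end of the occupied range.
#'
#' @param values numeric vector of intensities.
#' @param method `"otsu"` or `"triangle"`.
#' @param n_bins histogram bins; default 256.
#' @return a single threshold value; foreground is `values > threshold`.
#' @export
auto_threshold <- function(values, method = c("otsu", "triangle"),
                           n_bins = 256L) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1]) # flat image: empty foreground under '>'
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- as.numeric(tabulate(bin, nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  if (method == "otsu") {
    w <- cumsum(cnt); m <- cumsum(cnt * mids)
    n <- w[n_bins]; mt <- m[n_bins]
    k <- 1:(n_bins - 1L)
    w0 <- w[k]; w1 <- n - w0
    ok <- w0 > 0 & w1 > 0
    bc <- rep(-Inf, n_bins - 1L)
    bc[ok] <- (mt * w0[ok] / n - m[k][ok])^2 / (w0[ok] * w1[ok] / n)
    edges[which.max(bc) + 1L]
  } else {
    peak <- which.max(cnt)
    # run toward the longer tail
    lo <- min(which(cnt > 0)); hi <- max(which(cnt > 0))
    if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- peak; b <- lo }
    if (a == b) return(edges[a + 1L])
    ks <- a:b
    # distance from (k, cnt[k]) to the line (a, cnt[a]) - (b, 0)
    x1 <- a; y1 <- cnt[a]; x2 <- b; y2 <- cnt[b]
    d <- abs((y2 - y1) * ks - (x2 - x1) * cnt[ks] + x2 * y1 - y2 * x1)
    edges[ks[which.max(d)] + 1L]
  }
}

#' Detect microglia somata
#'
#' Automatic global thresholding of the cell channel followed by connected
#' components and a strict physical size filter. In 3D, component "area" is
#' the cross-section footprint in the z-slice closest to the component
#' centroid (mid-plane convention).
#'
#' @param iba1 numeric array (cell channel) or an [image_volume()] with an
#'   `iba1` channel.
#' @param voxel_size micrometre per voxel (ignored when `iba1` is an
#'   [image_volume()]).
#' @param params a [segmentation_params()] object.
#' @return list: `labels` (integer array; relabeled 1..n after filtering),
#'   `n_somata`, and `somata` (data frame with `soma_id`, `area_um2`,
#'   centroid coordinates in um).
#' @export
segment_somata <- function(iba1, voxel_size = NULL,
                           params = segmentation_params()) {
  if (inherits(iba1, "image_volume")) {
    voxel_size <- iba1$voxel_size
    iba1 <- iba1$channels$iba1
  }
  stopifnot(!is.null(voxel_size))
  if (!all(is.finite(iba1))) stop("cell channel must be finite")
  d <- dim(iba1)
  thr <- auto_threshold(as.numeric(iba1), params$threshold_method)
  fg <- iba1 > thr
  empty <- list(labels = array(0L, dim = d), n_somata = 0L,
                somata = data.frame(soma_id = integer(), area_um2 = numeric(),
                                    x_um = numeric(), y_um = numeric(),
                                    z_um = numeric()))
  if (!any(fg)) return(empty)
  lab <- label_components(fg)
  info <- component_areas(lab, voxel_size)
  keep <- info$area_um2 > params$soma_min_area
  if (!any(keep)) return(empty)
  kept_ids <- info$label[keep]
  newlab <- array(0L, dim = d)
  for (i in seq_along(kept_ids)) newlab[lab == kept_ids[i]] <- i
  somata <- data.frame(soma_id = seq_along(kept_ids),
                       area_um2 = info$area_um2[keep],
                       x_um = info$x_um[keep], y_um = info$y_um[keep],
                       z_um = info$z_um[keep])
  list(labels = newlab, n_somata = length(kept_ids), somata = somata)
}

# per-component mid-plane footprint area (um^2) and centroid (um)
component_areas <- function(lab, voxel_size) {
  d <- dim(lab)
  nd <- length(d)
  ids <- sort(unique(lab[lab > 0]))
  px <- voxel_size[1] * voxel_size[2]
  out <- data.frame(label = ids, area_um2 = NA_real_, x_um = NA_real_,
                    y_um = NA_real_, z_um = 0)
  idx_all <- which(lab > 0)
  co <- .vox_coords(idx_all, d)
  labv <- lab[idx_all]
  for (i in seq_along(ids)) {
    sel <- labv == ids[i]
    cc <- co[sel, , drop = FALSE]
    out$x_um[i] <- mean(cc[, 1] - 0.5) * voxel_size[1]
    out$y_um[i] <- mean(cc[, 2] - 0.5) * voxel_size[2]
    if (nd == 3L) {
      out$z_um[i] <- mean(cc[, 3] - 0.5) * voxel_size[3]
      zmid <- round(mean(cc[, 3]))
      inplane <- cc[cc[, 3] == zmid, , drop = FALSE]
      # distinct xy footprint in the mid plane
      out$area_um2[i] <- nrow(unique(inplane[, 1:2, drop = FALSE])) * px
    } else {
      out$area_um2[i] <- nrow(cc) * px
    }
  }
  out
}

#' Extract single-cell masks
#'
#' Thresholds the cell channel, assigns each foreground component to the
#' soma it contains, flags components containing two or more somata as
#' "touching" (excluded from single-cell morphometrics), and applies the
#' pixel-count size filter in the 2D human mode.
#'
#' @param iba1 numeric array or [image_volume()] with an `iba1` channel.
#' @param soma_labels labeled soma array from [segment_somata()].
#' @param voxel_size micrometre per voxel.
#' @param params a [segmentation_params()] object.
#' @param mode `"rodent-3d"` (no pixel filter) or `"human-2d"` (strict
#'   `> single_cell_min_size` pixels).
#' @return list of `cell_record` objects (fields `cell_id`, `mask`,
#'   `soma_mask`, `soma_id`, `soma_area_um2`, `centroid_um`, `touching`);
#'   touching cells are returned flagged but should be excluded downstream.
#' @export
extract_single_cells <- function(iba1, soma_labels, voxel_size = NULL,
                                 params = segmentation_params(),
                                 mode = c("rodent-3d", "human-2d")) {
  mode <- match.arg(mode)
  if (inherits(iba1, "image_volume")) {
    voxel_size <- iba1$voxel_size
    iba1 <- iba1$channels$iba1
  }
  stopifnot(!is.null(voxel_size))
  d <- dim(iba1)
  thr <- auto_threshold(as.numeric(iba1), params$threshold_method)
  fg <- iba1 > thr
  fg[soma_labels > 0] <- TRUE # somata always belong to the foreground
  lab <- label_components(fg)
  soma_ids <- sort(unique(soma_labels[soma_labels > 0]))
  if (length(soma_ids) == 0) return(list())
  # component hosting each soma (majority vote over soma voxels)
  host <- vapply(soma_ids, function(s) {
    comp <- lab[soma_labels == s]
    comp <- comp[comp > 0]
    if (length(comp) == 0) stop("soma ", s, " falls outside the foreground")
    as.integer(names(sort(table(comp), decreasing = TRUE))[1])
  }, integer(1))
  cells <- list()
  for (i in seq_along(soma_ids)) {
    s <- soma_ids[i]
    comp <- host[i]
    mask <- lab == comp
    if (mode == "human-2d" && sum(mask) <= params$single_cell_min_size) next
    touching <- sum(host == comp) >= 2
    soma_mask <- .refine_soma(iba1, mask, soma_labels == s, voxel_size)
    lab_soma <- array(as.integer(soma_mask), dim = d)
    soma_info <- component_areas(lab_soma, voxel_size)
    rec <- structure(list(cell_id = s,
                          mask = mask,
                          soma_mask = soma_mask,
                          soma_id = s,
                          soma_area_um2 = soma_info$area_um2[1],
                          centroid_um = unlist(soma_info[1, c("x_um", "y_um",
                                                              "z_um")]),
                          touching = touching),
                     class = "cell_record")
    cells[[length(cells) + 1L]] <- rec
  }
  cells
}

# Soma delineation inside a single cell: threshold the cell's own intensity
# histogram (Otsu) and keep the bright-core component containing the
# distance-transform maximum of the cell mask. Falls back to the detected
# soma label when the core is degenerate.
.refine_soma <- function(iba1, cell_mask, soma_label_mask, voxel_size) {
  vals <- iba1[cell_mask]
  thr <- auto_threshold(vals, "otsu")
  core <- cell_mask & iba1 > thr
  fallback <- soma_label_mask & cell_mask
  if (sum(core) < 9) return(if (any(fallback)) fallback else cell_mask)
  depth <- distance_transform(!cell_mask, voxel_size)
  peak <- which.max(ifelse(cell_mask, depth, -Inf))
  lab <- label_components(core)
  target <- lab[peak]
  if (target == 0) {
    # peak fell in a dim spot; take the core component with the deepest voxel
    depths <- tapply(depth[core], lab[core], max)
    target <- as.integer(names(which.max(depths)))
  }
  lab == target
}

#' Quantify IgG extravasation
#'
#' Fixed-threshold binarization (`intensity > igg_threshold`) with a strict
#' component-area filter, reported as the percentage of the field-of-view
#' area above threshold. A 3D stack is processed slice-wise so the area
#' convention matches the 2D definition.
#'
#' @param igg numeric array or [image_volume()] with an `igg` channel.
#' @param voxel_size micrometre per voxel.
#' @param params a [segmentation_params()] object.
#' @return leakage as percent of FOV area, in `[0, 100]`.
#' @export
quantify_igg <- function(igg, voxel_size = NULL,
                         params = segmentation_params()) {
  if (inherits(igg, "image_volume")) {
    voxel_size <- igg$voxel_size
    igg <- igg$channels$igg
  }
  stopifnot(!is.null(voxel_size))
  if (!all(is.finite(igg))) stop("leakage channel contains non-finite pixels")
  d <- dim(igg)
  px <- voxel_size[1] * voxel_size[2]
  slices <- if (length(d) == 3L) d[3] else 1L
  retained <- 0
  for (z in seq_len(slices)) {
    pl <- if (length(d) == 3L) igg[, , z] else igg
    fg <- pl > params$igg_threshold
    if (!any(fg)) next
    lab <- label_components(fg)
    cnt <- tabulate(lab[lab > 0])
    keep <- which(cnt * px > params$igg_min_area)
    if (length(keep)) retained <- retained + sum(cnt[keep])
  }
  100 * retained / prod(d)
}
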