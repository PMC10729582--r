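# Vessel enhancement and segmentation: multi-scale Frangi filtering with a
# self-tuned structure-contrast parameter (gamma set to a fraction of the
# maximum absolute Hessian eigenvalue over the image and all scales),
# followed by hysteresis thresholding whose low/high thresholds come from
# the three-class Otsu method applied to the vesselness distribution.

#' Frangi filter parameters
#'
#' @param scales filter scales in pixels; default `1:5`.
#' @param gamma_fraction fraction of the image-wide maximum absolute Hessian
#'   eigenvalue used as the structure-contrast parameter gamma; default 0.4.
#' @param alpha plate-vs-line discrimination weight (3D only); default 0.5.
#' @param beta blobness weight; default 0.5.
#' @return a `frangi_params` list.
#' @export
frangi_params <- function(scales = 1:5, gamma_fraction = 0.4,
                          alpha = 0.5, beta = 0.5) {
  scales <- as.numeric(scales)
  if (length(scales) < 1 || any(scales <= 0)) stop("scales must be positive")
  if (!(gamma_fraction > 0 && gamma_fraction <= 1))
    stop("gamma_fraction must lie in (0, 1]")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(scales = scales, gamma_fraction = gamma_fraction,
                 alpha = alpha, beta = beta), class = "frangi_params")
}

#' Scale-normalized Hessian eigenvalues of an image
#'
#' Smooths with an isotropic Gaussian of standard deviation `scale` (pixels),
#' takes central-difference second derivatives, multiplies by `scale^2`
#' (gamma-normalized derivatives), and returns the per-voxel eigenvalues
#' sorted by increasing absolute value.
#'
#' @param image numeric 2D or 3D array.
#' @param scale Gaussian scale in pixels (> 0).
#' @return list of arrays `lambda1`, `lambda2` (and `lambda3` in 3D), sorted
#'   so that `|lambda1| <= |lambda2| (<= |lambda3|)`.
#' @export
hessian_eigenvalues <- function(image, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("scale must be a single positive number")
  d <- dim(image)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  if (!all(is.finite(image))) stop("image must be finite")
  sm <- gauss_smooth_cpp(as.numeric(image), d, rep(scale, nd))
  s2 <- scale^2
  if (nd == 2L) {
    hxx <- diff_axis_cpp(sm, d, 0L, 2L) * s2
    hyy <- diff_axis_cpp(sm, d, 1L, 2L) * s2
    hxy <- diff_axis_cpp(diff_axis_cpp(sm, d, 0L, 1L), d, 1L, 1L) * s2
    # closed-form symmetric 2x2 eigenvalues
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    dim(l1) <- d; dim(l2) <- d
    list(lambda1 = l1, lambda2 = l2)
  } else {
    hxx <- diff_axis_cpp(sm, d, 0L, 2L) * s2
    hyy <- diff_axis_cpp(sm, d, 1L, 2L) * s2
    hzz <- diff_axis_cpp(sm, d, 2L, 2L) * s2
    hxy <- diff_axis_cpp(diff_axis_cpp(sm, d, 0L, 1L), d, 1L, 1L) * s2
    hxz <- diff_axis_cpp(diff_axis_cpp(sm, d, 0L, 1L), d, 2L, 1L) * s2
    hyz <- diff_axis_cpp(diff_axis_cpp(sm, d, 1L, 1L), d, 2L, 1L) * s2
    ev <- .sym3_eigenvalues(hxx, hyy, hzz, hxy, hxz, hyz)
    lapply(ev, function(e) { dim(e) <- d; e })
  }
}

# Vectorized eigenvalues of symmetric 3x3 matrices (trigonometric method),
# returned sorted by increasing |lambda|.
.sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  n <- length(a11)
  e1 <- e2 <- e3 <- rep(0, n)
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  e1[!nz] <- e2[!nz] <- e3[!nz] <- q[!nz]
  # sort each triple by |lambda|
  m <- cbind(e1, e2, e3)
  am <- abs(m)
  o1 <- max.col(-am, ties.method = "first")
  o3 <- max.col(am, ties.method = "last")
  same <- o1 == o3 # all equal magnitudes
  o3[same] <- (o1[same] %% 3L) + 1L
  o2 <- 6L - o1 - o3
  idx <- seq_len(nrow(m))
  list(lambda1 = m[cbind(idx, o1)],
       lambda2 = m[cbind(idx, o2)],
       lambda3 = m[cbind(idx, o3)])
}

#' Multi-scale Frangi vesselness
#'
#' Standard line-structure response for bright tubular structures on a dark
#' background, evaluated at each scale and combined by voxel-wise maximum.
#' The background-suppression parameter gamma is tuned per image:
#' `gamma = gamma_fraction * max |lambda|` over all voxels and scales.
#'
#' @param image numeric 2D or 3D array (vessel channel).
#' @param params a [frangi_params()] object.
#' @return numeric array of vesselness values in `[0, 1]`.
#' @export
frangi_vesselness <- function(image, params = frangi_params()) {
  stopifnot(inherits(params, "frangi_params"))
  d <- dim(image)
  nd <- length(d)
  # first pass: image-wide maximum |eigenvalue| across scales (self-tuning)
  ev_scales <- lapply(params$scales, function(s) hessian_eigenvalues(image, s))
  max_abs <- max(vapply(ev_scales, function(ev) {
    max(abs(ev[[length(ev)]]))
  }, numeric(1)))
  if (max_abs == 0) return(array(0, dim = d))
  gamma <- params$gamma_fraction * max_abs
  out <- array(0, dim = d)
  for (ev in ev_scales) {
    if (nd == 2L) {
      l1 <- ev$lambda1; l2 <- ev$lambda2
      s2 <- l1^2 + l2^2
      rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
      v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-s2 / (2 * gamma^2)))
      v[l2 >= 0] <- 0 # bright-on-dark polarity
    } else {
      l1 <- ev$lambda1; l2 <- ev$lambda2; l3 <- ev$lambda3
      s2 <- l1^2 + l2^2 + l3^2
      ra2 <- ifelse(l3 != 0, (l2 / l3)^2, 0)
      rb2 <- ifelse(l2 * l3 != 0, l1^2 / abs(l2 * l3), 0)
      v <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
        exp(-rb2 / (2 * params$beta^2)) *
        (1 - exp(-s2 / (2 * gamma^2)))
      v[l2 >= 0 | l3 >= 0] <- 0
    }
    out <- pmax(out, v)
  }
  dim(out) <- d
  out
}

#' Three-class Otsu thresholds
#'
#' Builds a 256-bin equal-width histogram over the finite value range and
#' exhaustively searches all two-threshold partitions for the pair maximizing
#' the between-class variance; ties are broken by the lexicographically
#' smallest `(low, high)`.
#'
#' @param values numeric vector (at least 3 distinct values).
#' @param n_bins histogram bins; default 256.
#' @return list with elements `low` and `high` (`low <= high`), on the scale
#'   of `values`.
#' @export
otsu3_thresholds <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3)
    stop("degenerate distribution: need at least 3 distinct values")
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- as.numeric(tabulate(bin, nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(cnt)
  m <- cumsum(cnt * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  best <- -Inf; bi <- bj <- NA_integer_
  for (i in 1:(n_bins - 2L)) {
    w0 <- w[i]
    if (w0 == 0) next
    m0 <- m[i]
    for (j in (i + 1L):(n_bins - 1L)) {
      w1 <- w[j] - w0
      if (w1 == 0) next
      w2 <- n - w[j]
      if (w2 == 0) next
      m1 <- m[j] - m0
      m2 <- mt - m[j]
      bc <- m0^2 / w0 + m1^2 / w1 + m2^2 / w2
      if (!is.finite(best) || bc > best + 1e-12 * max(1, abs(best))) {
        best <- bc; bi <- i; bj <- j
      }
    }
  }
  if (!is.finite(best)) stop("degenerate distribution: histogram collapsed")
  list(low = edges[bi + 1L], high = edges[bj + 1L])
}

#' Hysteresis segmentation
#'
#' Keeps every connected component of `{values > low}` that contains at
#' least one voxel with `values >= high`.
#'
#' @param vesselness numeric array.
#' @param thresholds list with `low` and `high`, `low <= high`.
#' @param connectivity `"full"` (default) or `"face"`.
#' @return logical array of the same shape.
#' @export
hysteresis_segment <- function(vesselness, thresholds,
                               connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  if (thresholds$low > thresholds$high) stop("low threshold exceeds high")
  weak <- vesselness > thresholds$low
  if (!any(weak)) return(array(FALSE, dim = dim(vesselness)))
  lab <- label_components(weak, connectivity)
  strong_labels <- unique(lab[vesselness >= thresholds$high & weak])
  strong_labels <- strong_labels[strong_labels > 0]
  out <- array(lab %in% strong_labels, dim = dim(vesselness))
  out
}

#' Segment vessels with self-tuned thresholds
#'
#' Frangi enhancement, three-class Otsu on the vesselness distribution, and
#' hysteresis segmentation; all intermediates are returned.
#'
#' @param image numeric array (vessel channel) or an [image_volume()] with a
#'   `vessel` channel.
#' @param params a [frangi_params()] object.
#' @param connectivity passed to [hysteresis_segment()].
#' @return a `vessel_segmentation` list: `vesselness`, `thresholds`, `mask`.
#' @export
segment_vessels <- function(image, params = frangi_params(),
                            connectivity = "full") {
  if (inherits(image, "image_volume")) {
    if (is.null(image$channels$vessel)) stop("no vessel channel present")
    image <- image$channels$vessel
  }
  v <- frangi_vesselness(image, params)
  if (all(v == 0)) {
    return(structure(list(vesselness = v,
                          thresholds = list(low = 0, high = 0),
                          mask = array(FALSE, dim = dim(v))),
                     class = "vessel_segmentation"))
  }
  th <- otsu3_thresholds(as.numeric(v))
  mask <- hysteresis_segment(v, th, connectivity)
  structure(list(vesselness = v, thresholds = th, mask = mask),
            class = "vessel_segmentation")
}
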