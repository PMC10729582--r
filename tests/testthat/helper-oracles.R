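# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force or closed form, sharing no code with the package
# internals.

# Exhaustive three-class Otsu: for every histogram bin pair, compute the
# between-class variance directly from the binned values.
oracle_otsu3 <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L; bin[bin > n_bins] <- n_bins
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  cnt <- as.numeric(tabulate(bin, n_bins))
  best <- -Inf; bl <- bh <- NA
  for (i in 1:(n_bins - 2)) {
    for (j in (i + 1):(n_bins - 1)) {
      w1 <- sum(cnt[1:i]); w2 <- sum(cnt[(i + 1):j]); w3 <- sum(cnt[(j + 1):n_bins])
      if (w1 == 0 || w2 == 0 || w3 == 0) next
      m1 <- sum(cnt[1:i] * mids[1:i]) / w1
      m2 <- sum(cnt[(i + 1):j] * mids[(i + 1):j]) / w2
      m3 <- sum(cnt[(j + 1):n_bins] * mids[(j + 1):n_bins]) / w3
      mt <- sum(cnt * mids) / sum(cnt)
      bc <- (w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2) / sum(cnt)
      if (bc > best + 1e-12) { best <- bc; bl <- edges[i + 1]; bh <- edges[j + 1] }
    }
  }
  list(low = bl, high = bh)
}

# Hysteresis by explicit flood fill from every strong voxel.
oracle_hysteresis <- function(v, low, high) {
  d <- dim(v)
  nd <- length(d)
  weak <- v > low
  out <- array(FALSE, dim = d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1,
                                dz = if (nd == 3) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  dims3 <- c(d, if (nd == 2) 1L)
  idx_of <- function(co) co[1] + (co[2] - 1) * dims3[1] +
    (co[3] - 1) * dims3[1] * dims3[2]
  seeds <- which(v >= high & weak)
  stack <- as.list(seeds)
  out[seeds] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    co <- arrayInd(p, dims3)[1, ]
    for (k in seq_len(nrow(offs))) {
      q <- co + c(offs[k, 1], offs[k, 2], offs[k, 3])
      if (any(q < 1) || any(q > dims3)) next
      qi <- idx_of(q)
      if (weak[qi] && !out[qi]) { out[qi] <- TRUE; stack[[length(stack) + 1]] <- qi }
    }
  }
  out
}

# Brute-force branch statistics: enumerate every simple path between nodes
# of degree != 2 whose interior nodes all have degree 2; dedupe by edge set.
oracle_branch_stats <- function(edges, lengths, n_nodes) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
  adj <- lapply(seq_len(n_nodes), function(v) {
    rows <- which(edges[, 1] == v | edges[, 2] == v)
    cbind(ifelse(edges[rows, 1] == v, edges[rows, 2], edges[rows, 1]), rows)
  })
  found <- list()
  terminals <- which(deg != 2 & deg > 0)
  for (v in terminals) {
    for (r in seq_len(nrow(adj[[v]]))) {
      len <- lengths[adj[[v]][r, 2]]
      eset <- adj[[v]][r, 2]
      cur <- adj[[v]][r, 1]
      while (deg[cur] == 2) {
        nn <- adj[[cur]]
        nxt <- nn[!(nn[, 2] %in% eset), , drop = FALSE]
        if (nrow(nxt) == 0) break
        len <- len + lengths[nxt[1, 2]]
        eset <- c(eset, nxt[1, 2])
        cur <- nxt[1, 1]
      }
      key <- paste(sort(eset), collapse = "-")
      found[[key]] <- len
    }
  }
  lens <- unname(unlist(found))
  list(n_endpoints = sum(deg == 1), n_branchpoints = sum(deg >= 3),
       branch_lengths = lens,
       max_branch_length = if (length(lens)) max(lens) else 0,
       total_branch_length = sum(lens))
}

# Random tree as an edge list with random positive edge lengths (node 1 is
# the root; each later node attaches to a uniformly chosen earlier node).
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  parents <- vapply(2:n_nodes, function(k) sample.int(k - 1, 1), integer(1))
  edges <- cbind(parents, 2:n_nodes)
  lengths <- runif(n_nodes - 1, 0.5, 10)
  list(edges = edges, lengths = lengths, n_nodes = n_nodes)
}

# Independent Gaussian smoothing (explicit kernel sums, reflected borders).
oracle_gauss_smooth_2d <- function(img, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  refl <- function(i, n) {
    period <- 2 * n - 2
    i <- ((i - 1) %% period + period) %% period
    ifelse(i < n, i + 1, period - i + 1)
  }
  tmp <- matrix(0, n, m); out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m)
    tmp[i, j] <- sum(k * img[refl(i + (-r:r), n), j])
  for (i in 1:n) for (j in 1:m)
    out[i, j] <- sum(k * tmp[i, refl(j + (-r:r), m)])
  out
}

# small utility: Dice coefficient of two masks
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# compact FOV configuration for fast unit tests
tiny_fov <- function(...) {
  args <- modifyList(list(shape = c(96, 96, 12), n_vessels = 2, n_cells = 4,
                          leakage_fraction = 0.04), list(...))
  do.call(fov_config, args)
}
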