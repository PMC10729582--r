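# Skeletonization of single-cell masks and graph-based branch statistics.
#
# The skeleton graph is an undirected graph over skeleton voxel centres
# (coordinates in um) with edge lengths equal to the Euclidean distance
# between voxel centres under the anisotropic voxel spacing. Endpoints are
# degree-1 nodes, branch points degree >= 3; branches are maximal paths
# whose interior nodes all have degree 2.

#' Build a skeleton graph from node coordinates and edges
#'
#' @param coords numeric matrix (n x 2 or n x 3) of node positions in um.
#' @param edges integer matrix (m x 2) of 1-based node indices.
#' @param lengths optional edge lengths in um; computed from `coords` when
#'   missing. (Contractions preserve original lengths, where recomputation
#'   from coordinates would distort them.)
#' @return a `skeleton_graph` with precomputed edge lengths and degrees.
#' @export
skeleton_graph <- function(coords, edges, lengths = NULL) {
  coords <- as.matrix(coords)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1 | edges > nrow(coords))) stop("edge index out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self loops are not allowed")
  }
  if (is.null(lengths)) {
    lengths <- if (nrow(edges)) {
      sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                    coords[edges[, 2], , drop = FALSE])^2))
    } else numeric()
  }
  if (length(lengths) != nrow(edges)) stop("one length per edge required")
  if (any(lengths <= 0)) stop("edge lengths must be positive")
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(coords))
  structure(list(coords = coords, edges = edges, lengths = lengths,
                 degree = deg), class = "skeleton_graph")
}

#' @export
#' @method print skeleton_graph
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> ", nrow(x$coords), " nodes, ", nrow(x$edges),
      " edges; ", sum(x$degree == 1), " endpoints, ",
      sum(x$degree >= 3), " branch points\n", sep = "")
  invisible(x)
}

# adjacency list: for each node, matrix of (neighbour, edge index)
.adjacency <- function(g) {
  adj <- vector("list", nrow(g$coords))
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1]; b <- g$edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  adj
}

#' Skeletonize a cell mask
#'
#' Topology-preserving thinning to a one-voxel-wide curve skeleton, graph
#' construction over skeleton voxels, optional contraction of all skeleton
#' nodes inside the soma mask to a single soma node, and pruning of terminal
#' spurs shorter than `prune_um`.
#'
#' @param mask logical array, one connected component.
#' @param voxel_size micrometre per voxel per axis.
#' @param soma_mask optional logical array; when given, skeleton nodes inside
#'   it are contracted to one node at the soma centroid, so processes are
#'   measured from the soma boundary outward.
#' @param prune_um prune terminal branches shorter than this length
#'   (default 1 um; artifacts of thinning at thick structures).
#' @return a `skeleton_graph`.
#' @export
skeletonize_cell <- function(mask, voxel_size, soma_mask = NULL,
                             prune_um = 1) {
  stopifnot(is.logical(mask))
  d <- dim(mask)
  stopifnot(length(voxel_size) == length(d))
  if (!any(mask)) stop("empty cell mask")
  lab <- label_components(mask)
  if (max(lab) > 1)
    stop("cell mask is disconnected (", max(lab), " components)")
  sk <- thin_cpp(mask, d)
  idx <- which(sk)
  co <- .vox_coords(idx, d)
  coords <- sweep(sweep(co, 2, 0.5), 2, voxel_size, "*")
  # edges: full-neighbourhood adjacency between skeleton voxels
  key <- as.numeric(idx)
  pos <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = pos)
  nd <- length(d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1,
                                dz = if (nd == 3) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- NULL
  dims3 <- c(d, if (nd == 2) 1L)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- co
    nb[, 1] <- nb[, 1] + o[1]; nb[, 2] <- nb[, 2] + o[2]
    if (nd == 3) nb[, 3] <- nb[, 3] + o[3]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2]
    if (nd == 3) ok <- ok & nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1]
    if (nd == 3) lin <- lin + (nb[ok, 3] - 1) * d[1] * d[2]
    src <- which(ok)
    for (j in seq_along(src)) {
      t <- mget(as.character(lin[j]), envir = pos, ifnotfound = list(NULL))[[1]]
      if (!is.null(t) && src[j] < t) edges <- rbind(edges, c(src[j], t))
    }
  }
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  g <- skeleton_graph(coords, edges)
  g <- .drop_diagonal_shortcuts(g)
  g <- .smooth_chains(g)
  if (!is.null(soma_mask) && any(soma_mask & sk)) {
    inside <- soma_mask[idx]
    g <- .contract_nodes(g, which(inside))
  }
  prune_spurs(g, prune_um)
}

# Laplacian smoothing of degree-2 chain nodes (junctions and endpoints stay
# fixed); suppresses the voxel-grid zigzag that inflates path lengths.
.smooth_chains <- function(g, iterations = 3, weight = 0.5) {
  if (nrow(g$edges) == 0) return(g)
  deg <- g$degree
  movable <- which(deg == 2L)
  if (length(movable) == 0) return(g)
  co <- g$coords
  nb1 <- rep(NA_integer_, nrow(co)); nb2 <- rep(NA_integer_, nrow(co))
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1]; b <- g$edges[e, 2]
    for (v in c(a, b)) {
      o <- if (v == a) b else a
      if (deg[v] == 2L) {
        if (is.na(nb1[v])) nb1[v] <- o else nb2[v] <- o
      }
    }
  }
  for (it in seq_len(iterations)) {
    mid <- (co[nb1[movable], , drop = FALSE] +
            co[nb2[movable], , drop = FALSE]) / 2
    co[movable, ] <- (1 - weight) * co[movable, , drop = FALSE] + weight * mid
  }
  skeleton_graph(co, g$edges)
}

# Remove the longest edge of every adjacency triangle (diagonal shortcut
# across an L-corner of the voxel skeleton); keeps connectivity.
.drop_diagonal_shortcuts <- function(g) {
  repeat {
    adj <- .adjacency(g)
    drop <- rep(FALSE, nrow(g$edges))
    ord <- order(g$lengths, decreasing = TRUE)
    changed <- FALSE
    for (e in ord) {
      if (drop[e]) next
      a <- g$edges[e, 1]; b <- g$edges[e, 2]
      na <- adj[[a]]; nb <- adj[[b]]
      if (is.null(na) || is.null(nb)) next
      common <- intersect(na[, 1], nb[, 1])
      for (c0 in common) {
        ea <- na[na[, 1] == c0, 2][1]
        eb <- nb[nb[, 1] == c0, 2][1]
        if (drop[ea] || drop[eb]) next
        if (g$lengths[e] >= g$lengths[ea] - 1e-12 &&
            g$lengths[e] >= g$lengths[eb] - 1e-12 &&
            (g$lengths[e] > g$lengths[ea] + 1e-12 ||
             g$lengths[e] > g$lengths[eb] + 1e-12)) {
          drop[e] <- TRUE; changed <- TRUE; break
        }
      }
    }
    if (!changed) break
    g <- skeleton_graph(g$coords, g$edges[!drop, , drop = FALSE])
  }
  g
}

# Contract a set of nodes into one node placed at their centroid; edges
# crossing into the contracted set keep their original length, parallel
# edges collapse to the shortest.
.contract_nodes <- function(g, nodes) {
  if (length(nodes) == 0) return(g)
  keep <- setdiff(seq_len(nrow(g$coords)), nodes)
  centroid <- colMeans(g$coords[nodes, , drop = FALSE])
  newid <- integer(nrow(g$coords))
  newid[keep] <- seq_along(keep)
  super <- length(keep) + 1L
  newid[nodes] <- super
  coords <- rbind(g$coords[keep, , drop = FALSE], centroid)
  e <- cbind(newid[g$edges[, 1]], newid[g$edges[, 2]])
  len <- g$lengths
  ok <- e[, 1] != e[, 2]
  e <- e[ok, , drop = FALSE]; len <- len[ok]
  if (nrow(e) == 0) return(skeleton_graph(coords, matrix(integer(), ncol = 2)))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  shortest <- tapply(len, key, min)
  first <- !duplicated(key)
  eu <- e[first, , drop = FALSE]
  skeleton_graph(coords, eu, lengths = as.numeric(shortest[key[first]]))
}

#' Branch statistics of a skeleton graph
#'
#' Branches are maximal paths between nodes of degree other than 2 (plus
#' isolated cycles); lengths are sums of edge lengths in um.
#'
#' @param skeleton a [skeleton_graph()].
#' @return list: `n_endpoints`, `n_branchpoints`, `branch_lengths` (um),
#'   `max_branch_length`, `total_branch_length`.
#' @export
branch_stats <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  g <- skeleton
  deg <- g$degree
  if (nrow(g$edges) == 0) {
    return(list(n_endpoints = 0L, n_branchpoints = 0L,
                branch_lengths = numeric(), max_branch_length = 0,
                total_branch_length = 0))
  }
  adj <- .adjacency(g)
  visited <- rep(FALSE, nrow(g$edges))
  lens <- numeric()
  nodes <- which(deg != 2)
  for (v in nodes) {
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      e <- nb[r, 2]
      if (visited[e]) next
      # walk through degree-2 chain
      len <- g$lengths[e]; visited[e] <- TRUE
      prev <- v; cur <- nb[r, 1]
      while (deg[cur] == 2) {
        nn <- adj[[cur]]
        nxt <- if (nn[1, 2] == e || visited[nn[1, 2]]) nn[2, ] else nn[1, ]
        if (visited[nxt[2]]) break
        e <- nxt[2]; visited[e] <- TRUE
        len <- len + g$lengths[e]
        prev <- cur; cur <- nxt[1]
      }
      lens <- c(lens, len)
    }
  }
  # leftover edges form pure degree-2 cycles
  while (any(!visited)) {
    e0 <- which(!visited)[1]
    visited[e0] <- TRUE
    len <- g$lengths[e0]
    start <- g$edges[e0, 1]; cur <- g$edges[e0, 2]; e <- e0
    while (cur != start) {
      nn <- adj[[cur]]
      nxt <- if (nn[1, 2] == e) nn[2, ] else nn[1, ]
      e <- nxt[2]; visited[e] <- TRUE
      len <- len + g$lengths[e]
      cur <- nxt[1]
    }
    lens <- c(lens, len)
  }
  list(n_endpoints = sum(deg == 1L),
       n_branchpoints = sum(deg >= 3L),
       branch_lengths = lens,
       max_branch_length = if (length(lens)) max(lens) else 0,
       total_branch_length = sum(lens))
}

#' Prune terminal spurs shorter than a length threshold
#'
#' Repeatedly removes endpoint-to-junction branches shorter than `prune_um`,
#' then collapses the now degree-2 chains implicitly by leaving the graph
#' untouched otherwise. Increasing `prune_um` can only reduce the number of
#' endpoints.
#'
#' @param skeleton a [skeleton_graph()].
#' @param prune_um length threshold in um (spurs strictly shorter are
#'   removed).
#' @return a pruned `skeleton_graph`.
#' @export
prune_spurs <- function(skeleton, prune_um = 1) {
  g <- skeleton
  if (prune_um <= 0) return(g)
  repeat {
    if (nrow(g$edges) == 0) return(g)
    deg <- g$degree
    adj <- .adjacency(g)
    drop_edges <- rep(FALSE, nrow(g$edges))
    removed_any <- FALSE
    for (v in which(deg == 1L)) {
      # walk from the endpoint to the first node of degree != 2
      e <- adj[[v]][1, 2]
      len <- g$lengths[e]
      path_edges <- e
      prev <- v; cur <- adj[[v]][1, 1]
      while (deg[cur] == 2L) {
        nn <- adj[[cur]]
        nxt <- if (nn[1, 2] == e) nn[2, ] else nn[1, ]
        e <- nxt[2]
        len <- len + g$lengths[e]
        path_edges <- c(path_edges, e)
        prev <- cur; cur <- nxt[1]
      }
      # only prune spurs hanging off a junction; keep isolated paths
      if (deg[cur] >= 3L && len < prune_um && !any(drop_edges[path_edges])) {
        drop_edges[path_edges] <- TRUE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(g)
    keep_e <- g$edges[!drop_edges, , drop = FALSE]
    used <- sort(unique(as.integer(keep_e)))
    if (length(used) == 0) {
      # keep the full graph rather than deleting the last structure
      return(g)
    }
    remap <- integer(nrow(g$coords)); remap[used] <- seq_along(used)
    g <- skeleton_graph(g$coords[used, , drop = FALSE],
                        cbind(remap[keep_e[, 1]], remap[keep_e[, 2]]),
                        lengths = g$lengths[!drop_edges])
  }
}
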