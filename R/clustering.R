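# Morphology clustering: z-scored features, Ward-linkage agglomerative
# clustering, UMAP embedding and per-stratum cluster frequencies.

#' Standardize a feature matrix to z-scores
#'
#' @param x numeric matrix or data frame of features (rows = cells).
#' @return matrix with column means 0 and standard deviations 1.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize")
  if (any(!is.finite(x))) stop("feature matrix contains missing values")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop("constant feature column: ", paste(bad, collapse = ", "))
  }
  scale(x)[, , drop = FALSE]
}

#' Ward-linkage hierarchical clustering
#'
#' Agglomerative clustering on Euclidean distances with Ward's
#' minimum-variance criterion (`hclust` method `ward.D2`), cut at `k`
#' clusters. The dendrogram and mean silhouette widths for a range of `k`
#' are returned alongside the labels, since the cluster count is an
#' empirical choice.
#'
#' @param x standardized feature matrix.
#' @param k number of clusters (default 4).
#' @param silhouette_k range of cluster counts for which mean silhouette
#'   width is reported; default `2:8`.
#' @return list: `labels` (integers `1..k`), `linkage` (the `hclust` tree),
#'   `k`, `silhouette` (data frame `k`, `mean_width`).
#' @export
ward_cluster <- function(x, k = 4, silhouette_k = 2:8) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  d <- dist(x, method = "euclidean")
  hc <- hclust(d, method = "ward.D2")
  labels <- cutree(hc, k = k)
  silhouette_k <- silhouette_k[silhouette_k >= 2 & silhouette_k < n]
  sil <- data.frame(k = silhouette_k,
                    mean_width = vapply(silhouette_k, function(kk) {
                      lb <- cutree(hc, k = kk)
                      mean(cluster::silhouette(lb, d)[, "sil_width"])
                    }, numeric(1)))
  list(labels = unname(labels), linkage = hc, k = k, silhouette = sil)
}

#' UMAP embedding of a feature matrix
#'
#' Deterministic for a fixed seed (single-threaded layout optimization).
#'
#' @param x standardized feature matrix.
#' @param n_neighbors UMAP neighbourhood size; default 15.
#' @param min_dist minimum embedding distance; default 0.1.
#' @param seed random seed; default 42.
#' @return numeric matrix (n x 2) with columns `umap1`, `umap2`.
#' @export
umap_embed <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 42) {
  x <- as.matrix(x)
  if (nrow(x) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 rows for UMAP")
  emb <- .with_seed(seed, uwot::umap(x, n_neighbors = n_neighbors,
                                     min_dist = min_dist, n_threads = 1,
                                     n_sgd_threads = 0, batch = FALSE))
  colnames(emb) <- c("umap1", "umap2")
  emb
}

#' Cluster frequencies per stratum
#'
#' @param labels integer cluster labels.
#' @param strata factor-like vector of the same length (group, region or
#'   hypertension stage per cell).
#' @return data frame of relative frequencies: one row per stratum, one
#'   column per cluster; rows sum to 1. Empty strata are dropped with a
#'   warning.
#' @export
cluster_frequencies <- function(labels, strata) {
  stopifnot(length(labels) == length(strata))
  if (!is.factor(strata)) strata <- factor(strata)
  empty <- setdiff(levels(strata), unique(as.character(strata)))
  if (length(empty))
    warning("empty strata omitted: ", paste(empty, collapse = ", "))
  tab <- table(droplevels(strata), factor(labels, levels = sort(unique(labels))))
  freq <- prop.table(tab, margin = 1)
  out <- as.data.frame.matrix(freq)
  colnames(out) <- paste0("cluster_", colnames(out))
  cbind(stratum = rownames(out), out, row.names = NULL)
}

#' Cluster morphologies end to end
#'
#' Standardize, Ward-cluster, embed with UMAP and tabulate frequencies.
#'
#' @param features data frame with the 8 morphology feature columns plus
#'   metadata columns.
#' @param feature_cols names of the feature columns; defaults to the 8
#'   morphology features.
#' @param k cluster count (default 4).
#' @param by optional metadata column name for frequency tables.
#' @param seed UMAP seed.
#' @return list: `labels`, `linkage`, `embedding`, `silhouette`,
#'   `frequencies` (NULL when `by` is missing).
#' @export
cluster_morphologies <- function(features,
                                 feature_cols = c("soma_area_um2",
                                                  "n_endpoints",
                                                  "n_branchpoints",
                                                  "max_branch_length_um",
                                                  "total_branch_length_um",
                                                  "cell_volume", "hull_volume",
                                                  "ramification_index"),
                                 k = 4, by = NULL, seed = 42) {
  x <- standardize_features(features[, feature_cols, drop = FALSE])
  cl <- ward_cluster(x, k = k)
  nn <- min(15, nrow(x) - 1)
  emb <- umap_embed(x, n_neighbors = nn, seed = seed)
  freq <- if (!is.null(by)) cluster_frequencies(cl$labels, features[[by]])
  list(labels = cl$labels, linkage = cl$linkage, embedding = emb,
       silhouette = cl$silhouette, frequencies = freq)
}
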