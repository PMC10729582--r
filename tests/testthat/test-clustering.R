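# Feature standardization, Ward clustering, UMAP and frequency tables.

test_that("standardize_features: z-scores, constant columns, idempotence", {
  set.seed(2)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  z <- standardize_features(x)
  expect_true(all(abs(colMeans(z)) < 1e-8))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-8))
  expect_equal(unclass(standardize_features(z)), unclass(z),
               tolerance = 1e-10, ignore_attr = TRUE)

  x[, 2] <- 5
  expect_error(standardize_features(x), "constant feature column: b")
  expect_error(standardize_features(x[1, , drop = FALSE]), "at least 2")
})

test_that("ward_cluster: degenerate k, separation recovery, monotone heights", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(ward_cluster(x, k = 1)$labels, rep(1L, 20))
  expect_equal(sort(unique(ward_cluster(x, k = 20)$labels)), 1:20)
  expect_error(ward_cluster(x, k = 21), "k must lie")

  blobs <- rbind(matrix(rnorm(150), 50, 3),
                 matrix(rnorm(150, mean = 10), 50, 3))
  cl <- ward_cluster(standardize_features(blobs), k = 2)
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_true(all(diff(cl$linkage$height) >= -1e-10))
})

test_that("cluster labels are invariant to row permutation", {
  af <- archetype_features(15, seed = 6)
  x <- standardize_features(af[, -1])
  set.seed(9)
  perm <- sample(nrow(x))
  l1 <- ward_cluster(x, k = 4)$labels
  l2 <- ward_cluster(x[perm, ], k = 4)$labels
  expect_equal(mclust::adjustedRandIndex(l1[perm], l2), 1)
})

test_that("umap_embed: shape, determinism, minimum size", {
  af <- archetype_features(12, seed = 1)
  x <- standardize_features(af[, -1])
  e1 <- umap_embed(x, n_neighbors = 10, seed = 42)
  expect_equal(dim(e1), c(nrow(x), 2))
  e2 <- umap_embed(x, n_neighbors = 10, seed = 42)
  expect_identical(e1, e2)
  expect_error(umap_embed(x[1:5, ], n_neighbors = 10), "n_neighbors")
})

test_that("cluster_frequencies normalizes within strata", {
  labs <- c(1, 1, 2, 2, 1, 2)
  strat <- c("a", "a", "a", "b", "b", "b")
  f <- cluster_frequencies(labs, strat)
  expect_equal(rowSums(f[, -1]), c(1, 1), ignore_attr = TRUE)
  expect_equal(f$cluster_1[f$stratum == "a"], 2 / 3)

  one <- cluster_frequencies(rep(1, 6), strat)
  expect_true(all(one$cluster_1 == 1))

  balanced <- cluster_frequencies(rep(c(1, 2), 10), rep(c("a", "b"), each = 10))
  expect_true(all(abs(as.matrix(balanced[, -1]) - 0.5) < 1e-12))

  expect_warning(cluster_frequencies(labs, factor(strat, levels = c("a", "b", "c"))),
                 "empty strata")
})

test_that("archetype features are recovered end to end", {
  af <- archetype_features(30, seed = 11)
  res <- cluster_morphologies(af, k = 4, by = "archetype", seed = 42)
  expect_gte(mclust::adjustedRandIndex(res$labels, af$archetype), 0.8)
  expect_equal(dim(res$embedding), c(120, 2))
  expect_true(all(abs(rowSums(as.matrix(res$frequencies[, -1])) - 1) < 1e-12))
  expect_true(is.data.frame(res$silhouette) && nrow(res$silhouette) > 0)
})
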