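# Soma detection, single-cell extraction and IgG quantification.

test_that("segmentation_params validates ranges", {
  expect_error(segmentation_params(soma_min_area = -1), "positive")
  expect_error(segmentation_params(igg_threshold = 300), "8-bit")
})

test_that("segment_somata: blank image, count recovery, strict size filter", {
  blank <- array(0, dim = c(32, 32))
  expect_equal(segment_somata(blank, c(1, 1))$n_somata, 0)

  # 7 discs of ~100 um^2 and 3 of ~20 um^2 at 1 um pixels: filter > 60 keeps 7
  img <- array(0, dim = c(128, 128))
  centers_big <- cbind(c(20, 20, 20, 64, 64, 108, 108), c(20, 64, 108, 20, 108, 42, 86))
  centers_small <- cbind(c(64, 90, 40), c(64, 64, 64) + 40)
  xy <- as.matrix(expand.grid(1:128, 1:128))
  for (k in 1:7) {
    d2 <- (xy[, 1] - centers_big[k, 1])^2 + (xy[, 2] - centers_big[k, 2])^2
    img[d2 <= 5.6^2] <- 200 # area ~ 98 um^2
  }
  for (k in 1:3) {
    d2 <- (xy[, 1] - centers_small[k, 1])^2 + (xy[, 2] - centers_small[k, 2])^2
    img[d2 <= 2.5^2] <- 200 # area ~ 20 um^2
  }
  res <- segment_somata(img, c(1, 1))
  expect_equal(res$n_somata, 7)
  expect_true(all(res$somata$area_um2 > 60))

  # exactly 60 um^2 is excluded (strict inequality)
  sq <- array(0, dim = c(64, 64))
  sq[10:19, 10:15] <- 200 # 10 x 6 = 60 px = 60 um^2
  sq[40:52, 40:52] <- 200 # 169 um^2 companion so thresholding is non-trivial
  res2 <- segment_somata(sq, c(1, 1))
  expect_equal(res2$n_somata, 1)
  expect_equal(res2$somata$area_um2, 169)
})

test_that("segment_somata recovers rendered somata in 3D", {
  cfg <- tiny_fov(n_cells = 5, vam_fraction = 0, seed = 21)
  sim <- simulate_fov(cfg, "f")
  res <- segment_somata(sim$clean$iba1, cfg$voxel_size)
  expect_equal(res$n_somata, 5)
  tr <- sort(sim$truth$cells$cells$soma_area_um2)
  got <- sort(res$somata$area_um2)
  expect_true(all(abs(got - tr) / tr <= 0.1))
})

test_that("extract_single_cells: isolated recovery, touching exclusion, human filter", {
  cfg <- tiny_fov(n_cells = 3, vam_fraction = 0, seed = 31)
  sim <- simulate_fov(cfg, "f")
  som <- segment_somata(sim$clean$iba1, cfg$voxel_size)
  cells <- extract_single_cells(sim$clean$iba1, som$labels, cfg$voxel_size)
  expect_equal(length(cells), som$n_somata)
  expect_true(all(vapply(cells, function(cl) sum(cl$soma_mask & !cl$mask) == 0,
                         logical(1))))

  # two overlapping discs sharing one component -> both flagged touching
  img <- array(0, dim = c(64, 64))
  xy <- as.matrix(expand.grid(1:64, 1:64))
  img[(xy[, 1] - 28)^2 + (xy[, 2] - 32)^2 <= 81] <- 200
  img[(xy[, 1] - 40)^2 + (xy[, 2] - 32)^2 <= 81] <- 200
  labs <- array(0L, dim = c(64, 64))
  labs[(xy[, 1] - 28)^2 + (xy[, 2] - 32)^2 <= 16] <- 1L
  labs[(xy[, 1] - 40)^2 + (xy[, 2] - 32)^2 <= 16] <- 2L
  touching <- extract_single_cells(img, labs, c(1, 1))
  expect_equal(length(touching), 2)
  expect_true(all(vapply(touching, `[[`, logical(1), "touching")))
  expect_equal(nrow(morphology_table(touching, c(1, 1))), 0)

  # human 2D mode: a 1500-pixel component fails the > 2000 px filter
  img2 <- array(0, dim = c(128, 128))
  img2[10:59, 10:39] <- 180 # 50 x 30 = 1500 px
  img2[70:119, 60:109] <- 180 # 2500 px companion
  labs2 <- array(0L, dim = c(128, 128))
  labs2[30:34, 20:24] <- 1L
  labs2[90:94, 80:84] <- 2L
  human <- extract_single_cells(img2, labs2, c(0.3, 0.3),
                                params = segmentation_params(threshold_method = "triangle"),
                                mode = "human-2d")
  expect_equal(length(human), 1)
  expect_equal(human[[1]]$cell_id, 2)
})

test_that("quantify_igg: zero, planted recovery, strict area filter, range", {
  expect_equal(quantify_igg(array(0, dim = c(32, 32)), c(1, 1)), 0)
  expect_error(quantify_igg(array(NA_real_, dim = c(4, 4)), c(1, 1)), "finite")

  # single 4 um^2 blob above threshold is removed by the > 5 um^2 filter
  img <- array(0, dim = c(64, 64))
  img[10:11, 10:11] <- 200 # 4 px at 1 um^2/px
  expect_equal(quantify_igg(img, c(1, 1)), 0)
  img[30:35, 30:35] <- 200 # 36 um^2 survives
  expect_equal(quantify_igg(img, c(1, 1)), 100 * 36 / (64 * 64))

  cfg <- fov_config(shape = c(96, 96, 16), n_vessels = 6,
                    vessel_radius_range = c(3, 5), leakage_fraction = 0.25,
                    n_cells = 0, seed = 14)
  sim <- simulate_fov(cfg, "f")
  got <- quantify_igg(sim$clean$igg, cfg$voxel_size)
  expect_lt(abs(got - 100 * sim$truth$true_leakage_fraction), 2)
  expect_true(got >= 0 && got <= 100)
})

test_that("IgG percentage is monotone in threshold and area filter", {
  cfg <- tiny_fov(seed = 19)
  sim <- simulate_fov(cfg, "f")
  igg <- sim$volume$channels$igg
  p_base <- quantify_igg(igg, cfg$voxel_size)
  p_hi <- quantify_igg(igg, cfg$voxel_size,
                       segmentation_params(igg_threshold = 60))
  p_area <- quantify_igg(igg, cfg$voxel_size,
                         segmentation_params(igg_min_area = 50))
  expect_lte(p_hi, p_base)
  expect_lte(p_area, p_base)
})
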