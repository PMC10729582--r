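# Synthetic FOV generator: configuration contracts, determinism, geometry
# and ground-truth consistency.

test_that("fov_config validates its invariants", {
  expect_s3_class(fov_config(), "fov_config")
  expect_error(fov_config(shape = c(0, 10, 5)), "strictly positive")
  expect_error(fov_config(voxel_size = c(1, -1, 1)), "strictly positive")
  expect_error(fov_config(vam_fraction = 1.5), "vam_fraction")
  expect_error(fov_config(leakage_fraction = -0.1), "leakage_fraction")
  expect_error(fov_config(n_cells = -1), ">= 0")
  expect_error(fov_config(noise = list(sigma = -2)), "sigma")
})

test_that("vessel generation: empty case, determinism, cylinder volume", {
  cfg0 <- tiny_fov(n_vessels = 0)
  v0 <- generate_vessels(cfg0)
  expect_true(all(v0$channel == 0))
  expect_false(any(v0$truth$mask))

  cfg <- tiny_fov(seed = 5)
  a <- generate_vessels(cfg)
  b <- generate_vessels(cfg)
  expect_identical(a$channel, b$channel)
  expect_identical(a$truth$mask, b$truth$mask)

  # straight tube of radius 2 um along x: voxelized volume vs pi r^2 L
  cfg2 <- fov_config(shape = c(80, 40, 40), voxel_size = c(0.5, 0.5, 0.5),
                     n_vessels = 0)
  ctr <- c(20, 10, 10) # um
  ends <- c(0, 40)
  cp <- microvam:::.capsule_patch(cfg2, c(ends[1], ctr[2], ctr[3]),
                                  c(ends[2], ctr[2], ctr[3]), 4)
  mask <- array(FALSE, dim = cfg2$shape)
  mask[cp$ix, cp$iy, cp$iz] <- cp$dist <= 2
  vol <- sum(mask) * prod(cfg2$voxel_size)
  expect_lt(abs(vol - pi * 4 * 40) / (pi * 4 * 40), 0.1)
})

test_that("microglia generation honors counts, degenerate trees and VAM planting", {
  cfg <- tiny_fov(n_cells = 10, vam_fraction = 0, seed = 3)
  mic <- generate_microglia(cfg)
  expect_equal(nrow(mic$truth$cells), 10)

  cfg0 <- tiny_fov(n_cells = 3, branches_per_cell = c(0, 0), vam_fraction = 0,
                   seed = 4)
  mic0 <- generate_microglia(cfg0)
  expect_true(all(mic0$truth$cells$n_endpoints == 0))
  for (i in 1:3)
    expect_identical(mic0$truth$masks[[i]], mic0$truth$soma_masks[[i]])

  cfg1 <- tiny_fov(n_cells = 4, n_vessels = 3, vam_fraction = 1, seed = 6)
  ves <- generate_vessels(cfg1)
  mic1 <- generate_microglia(cfg1, ves$truth)
  expect_true(all(mic1$truth$cells$is_vam))
  # every soma intersects the one-voxel-dilated vessel mask
  dil <- distance_transform(ves$truth$mask, cfg1$voxel_size) <=
    sqrt(sum(cfg1$voxel_size^2))
  for (i in 1:4) expect_true(any(mic1$truth$soma_masks[[i]] & dil))
})

test_that("microglia truth is consistent with the rendered masks", {
  cfg <- tiny_fov(n_cells = 4, vam_fraction = 0, seed = 9)
  mic <- generate_microglia(cfg)
  for (i in seq_len(4)) {
    soma <- mic$truth$soma_masks[[i]]
    info <- microvam:::component_areas(array(as.integer(soma), dim = dim(soma)),
                                       cfg$voxel_size)
    expect_equal(info$area_um2[1], mic$truth$cells$soma_area_um2[i])
    expect_true(all(soma[mic$truth$masks[[i]] == FALSE] == FALSE)) # soma in cell
  }
})

test_that("leakage generation hits its target and is deterministic", {
  cfg <- tiny_fov(leakage_fraction = 0, seed = 2)
  l0 <- generate_leakage(cfg)
  expect_equal(l0$true_leakage_fraction, 0)
  expect_true(all(l0$channel == 0))

  cfg1 <- fov_config(shape = c(96, 96, 16), n_vessels = 6,
                     vessel_radius_range = c(3, 5), leakage_fraction = 0.25,
                     n_cells = 0, seed = 8)
  ves <- generate_vessels(cfg1)
  l1 <- generate_leakage(cfg1, ves$truth)
  expect_lt(abs(l1$true_leakage_fraction - 0.25), 0.02)
  # achieved fraction equals a direct recount of the clean channel
  recount <- mean(l1$channel + 0.8 * cfg1$background > cfg1$igg_threshold)
  expect_equal(l1$true_leakage_fraction, recount)

  l2 <- generate_leakage(cfg1, ves$truth)
  expect_identical(l1$channel, l2$channel)
})

test_that("leakage warns when the target is unreachable", {
  cfg <- fov_config(shape = c(48, 48, 8), n_vessels = 1,
                    vessel_radius_range = c(2, 2), leakage_fraction = 0.9,
                    n_cells = 0, seed = 1)
  ves <- generate_vessels(cfg)
  expect_warning(res <- generate_leakage(cfg, ves$truth), "not achievable")
  expect_lt(res$true_leakage_fraction, 0.9)
})

test_that("add_noise contracts: identity, CLT bound, clipping, errors", {
  img <- array(100, dim = c(50, 50))
  expect_identical(add_noise(img, sigma = 0, poisson = FALSE), img)
  expect_error(add_noise(img, sigma = -1), "sigma")

  noisy <- add_noise(img, sigma = 5, poisson = FALSE, seed = 42)
  n <- length(img)
  expect_lt(abs(mean(noisy) - 100), 3 * 5 / sqrt(n) + 0.5) # 0.5 for rounding
  expect_true(all(noisy >= 0 & noisy <= 255))

  bright <- array(254, dim = c(30, 30))
  expect_true(all(add_noise(bright, sigma = 20, seed = 1) <= 255))
})

test_that("a full FOV is bit-reproducible under its seed", {
  cfg <- tiny_fov(seed = 77)
  s1 <- simulate_fov(cfg, "f")
  s2 <- simulate_fov(cfg, "f")
  for (ch in names(s1$volume$channels))
    expect_identical(s1$volume$channels[[ch]], s2$volume$channels[[ch]])
  expect_identical(s1$truth$cells$cells, s2$truth$cells$cells)
})

test_that("TIFF round trip preserves channels, shape and voxel size", {
  cfg <- tiny_fov(seed = 13)
  sim <- simulate_fov(cfg, "f")
  path <- file.path(tempdir(), "roundtrip.tif")
  write_fov_tiff(sim$volume, path)
  back <- read_fov_tiff(path)
  expect_identical(back$dim, sim$volume$dim)
  expect_equal(back$voxel_size, sim$volume$voxel_size)
  for (ch in names(sim$volume$channels))
    expect_identical(back$channels[[ch]], sim$volume$channels[[ch]])
  unlink(c(path, paste0(path, ".json")))
})
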