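# Frangi enhancement, three-class Otsu, hysteresis segmentation.

test_that("hessian_eigenvalues: analytic and oracle agreement", {
  expect_error(hessian_eigenvalues(matrix(0, 8, 8), scale = 0), "positive")

  const <- matrix(3, 16, 16)
  ev <- hessian_eigenvalues(const, 1)
  expect_true(all(ev$lambda1 == 0) && all(ev$lambda2 == 0))

  # separable quadratic x^2: lambda pair (0, 2) in the interior at scale 1
  quad <- matrix(rep((1:32)^2, 32), 32, 32)
  ev <- hessian_eigenvalues(quad, 1)
  expect_lt(max(abs(ev$lambda1[10:22, 10:22])), 1e-8)
  expect_lt(max(abs(ev$lambda2[10:22, 10:22] - 2)), 1e-6)

  # random smooth image: must match independent FD + eigen() oracle
  set.seed(42)
  img <- oracle_gauss_smooth_2d(matrix(rnorm(32 * 32), 32), 2) * 50
  s <- 1.5
  ev <- hessian_eigenvalues(img, s)
  sm <- oracle_gauss_smooth_2d(img, s)
  for (i in 5:28) for (j in 5:28) {
    hxx <- (sm[i + 1, j] - 2 * sm[i, j] + sm[i - 1, j]) * s^2
    hyy <- (sm[i, j + 1] - 2 * sm[i, j] + sm[i, j - 1]) * s^2
    hxy <- (sm[i + 1, j + 1] - sm[i + 1, j - 1] -
            sm[i - 1, j + 1] + sm[i - 1, j - 1]) / 4 * s^2
    lam <- sort(eigen(matrix(c(hxx, hxy, hxy, hyy), 2), symmetric = TRUE,
                      only.values = TRUE)$values)
    got <- sort(c(ev$lambda1[i, j], ev$lambda2[i, j]))
    expect_lt(max(abs(got - lam)) / max(abs(lam), 1e-6), 1e-6)
  }
})

test_that("frangi_vesselness: range, structure selectivity, invariances", {
  expect_error(frangi_params(scales = c(0, 1)), "positive")
  expect_error(frangi_params(gamma_fraction = 1.5), "gamma_fraction")

  const <- array(7, dim = c(24, 24, 8))
  expect_true(all(frangi_vesselness(const) == 0))

  # 2D tube of radius 2 px: centerline response beats far background
  n <- 64
  xy <- expand.grid(x = 1:n, y = 1:n)
  tube <- matrix(200 * exp(-((xy$x - 32)^2) / (2 * 2^2)), n, n) + 10
  v <- frangi_vesselness(tube)
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(min(v[32, 16:48]), max(v[c(10, 54), 16:48]))

  # isotropic blob responds less than an equal-contrast tube at its center
  blob <- matrix(200 * exp(-((xy$x - 32)^2 + (xy$y - 32)^2) / (2 * 2^2)), n, n) + 10
  vb <- frangi_vesselness(blob)
  expect_lt(vb[32, 32], v[32, 32])

  # invariant to additive offset; equivariant under 90-degree rotation
  v_off <- frangi_vesselness(tube + 50)
  expect_equal(v, v_off, tolerance = 1e-10)
  rot <- t(tube)[, n:1]
  v_rot <- frangi_vesselness(rot)
  expect_equal(v_rot, t(v)[, n:1], tolerance = 1e-10)
})

test_that("otsu3_thresholds matches the exhaustive oracle", {
  vals <- rep(c(0, 0.5, 1), each = 100)
  th <- otsu3_thresholds(vals)
  expect_true(th$low > 0 && th$low <= 0.5 && th$high > 0.5 && th$high <= 1)

  expect_error(otsu3_thresholds(rep(1, 50)), "degenerate")
  expect_error(otsu3_thresholds(c(1, 2)), "degenerate")

  set.seed(1)
  for (rep in 1:5) {
    x <- switch(1 + rep %% 3,
                runif(10000),
                c(rnorm(5000, 0, 1), rnorm(3000, 5, 0.5), rnorm(2000, 10, 1)),
                rexp(10000))
    got <- otsu3_thresholds(x)
    want <- oracle_otsu3(x)
    expect_equal(got$low, want$low)
    expect_equal(got$high, want$high)
  }
})

test_that("hysteresis_segment: contracts and flood-fill oracle", {
  v <- array(0.2, dim = c(8, 8))
  expect_false(any(hysteresis_segment(v, list(low = 0.5, high = 0.8))))
  expect_error(hysteresis_segment(v, list(low = 0.9, high = 0.1)), "exceeds")

  # one weak component with a single strong voxel is kept whole
  v2 <- array(0, dim = c(10, 10))
  v2[3:7, 5] <- 0.4
  v2[5, 5] <- 0.9
  m <- hysteresis_segment(v2, list(low = 0.3, high = 0.8))
  expect_true(all(m[3:7, 5]))
  expect_equal(sum(m), 5)

  set.seed(7)
  for (rep in 1:5) {
    v3 <- array(runif(16^3), dim = c(16, 16, 16))
    th <- list(low = 0.6, high = 0.93)
    expect_identical(hysteresis_segment(v3, th),
                     oracle_hysteresis(v3, th$low, th$high))
  }
})

test_that("mask grows monotonically as the low threshold drops", {
  set.seed(3)
  v <- array(runif(16^3), dim = c(16, 16, 16))
  m1 <- hysteresis_segment(v, list(low = 0.7, high = 0.95))
  m2 <- hysteresis_segment(v, list(low = 0.5, high = 0.95))
  expect_true(all(m2[m1]))
})

test_that("segment_vessels recovers synthetic networks", {
  blank <- array(5, dim = c(32, 32, 8))
  expect_false(any(segment_vessels(blank)$mask))

  cfg <- fov_config(seed = 4)
  ves <- generate_vessels(cfg)
  img <- ves$channel + cfg$background
  seg <- segment_vessels(img)
  # smoke-level bound for one FOV; the acceptance suite checks the full
  # recovery criterion as a multi-FOV mean
  expect_gte(dice(seg$mask, ves$truth$mask), 0.7)
  # every mask component contains a strong voxel; mask within the weak set
  expect_true(all(seg$vesselness[seg$mask] > seg$thresholds$low))

  noisy <- add_noise(img, sigma = 3, poisson = FALSE, seed = 5)
  segn <- segment_vessels(noisy)
  expect_lt(abs(dice(segn$mask, ves$truth$mask) -
                dice(seg$mask, ves$truth$mask)), 0.1)
})
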