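# Statistical layer: normality, Welch t, two-way ANOVA with Holm-Sidak,
# Spearman matrices and relative qPCR quantification.

test_that("shapiro_normality: calibration on normal draws and guards", {
  set.seed(101)
  res <- shapiro_normality(rnorm(5000))
  expect_gt(res$p, 0.01)
  expect_true(res$statistic > 0 && res$statistic <= 1)
  expect_error(shapiro_normality(c(1, 2)), "at least 3")
  expect_error(shapiro_normality(rep(2, 10)), "zero variance")
})

test_that("welch_t: identical groups, separation, symmetry", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  set.seed(7)
  x <- c(0, 0, 0, 0) + rnorm(4, 0, 1e-3)
  y <- c(1, 1, 1, 1) + rnorm(4, 0, 1e-3)
  r <- welch_t(x, y)
  expect_lt(r$p, 0.01)
  # closed-form Welch formula
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 4)
  expect_equal(r$statistic, tw, tolerance = 1e-12)

  r2 <- welch_t(y, x)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p, r$p)

  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("welch_t reduces to Student t for equal sizes and variances", {
  set.seed(12)
  x <- rnorm(12); y <- rnorm(12)
  # force exactly equal sample variances by scaling
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)
  w <- welch_t(x, y)
  s <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$statistic, unname(s$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(s$parameter), tolerance = 1e-10)
  expect_equal(w$p, s$p.value, tolerance = 1e-10)
})

test_that("holm_sidak closed form, monotonicity and dominance", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  p <- c(0.2, 0.01, 0.8, 0.03, 0.5)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_equal(holm_sidak(0.05), 0.05) # single test unchanged
})

test_that("two-way ANOVA isolates a pure age effect and adjusts post hocs", {
  set.seed(31)
  d <- expand.grid(group = c("ctrl", "htn"), age = c("young", "old"),
                   rep = 1:6)
  d$y <- ifelse(d$age == "old", 3, 0) + rnorm(nrow(d), 0, 0.25)
  res <- anova2_holm_sidak(d$y, d$group, d$age)
  a <- res$anova
  expect_lt(a$F[a$effect == "group"], 1)
  expect_lt(a$p[a$effect == "age"], 0.01)
  expect_gt(a$p[a$effect == "group:age"], 0.05)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw))

  # closed-form oracle: balanced design sums of squares
  cell_means <- tapply(d$y, list(d$group, d$age), mean)
  n_cell <- 6
  ss_age <- 2 * n_cell * sum((colMeans(cell_means) - mean(d$y))^2)
  ms_res <- sum((d$y - ave(d$y, d$group, d$age))^2) / (nrow(d) - 4)
  expect_equal(a$F[a$effect == "age"], ss_age / ms_res, tolerance = 1e-8)

  expect_error(anova2_holm_sidak(d$y, rep("x", nrow(d)), d$age), "2 levels")
})

test_that("spearman_matrix: monotone transforms, ties oracle, exact p", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 6, 7.7, 9, 10.5, 12, 13, 14)
  m <- spearman_matrix(cbind(x = x, ex = exp(x), neg = -x))
  expect_equal(m$rho["x", "ex"], 1)
  expect_equal(m$rho["x", "neg"], -1)
  expect_true(isSymmetric(m$rho))

  # ties: average-rank Pearson oracle
  set.seed(3)
  a <- sample(1:5, 15, replace = TRUE)
  b <- sample(1:4, 15, replace = TRUE)
  m2 <- spearman_matrix(cbind(a = a, b = b))
  expect_equal(m2$rho["a", "b"], cor(rank(a), rank(b)), tolerance = 1e-12)

  # exact permutation p for small n agrees with cor.test
  set.seed(5)
  u <- rnorm(8); v <- rnorm(8)
  m3 <- spearman_matrix(cbind(u = u, v = v))
  ct <- cor.test(u, v, method = "spearman", exact = TRUE)
  expect_equal(m3$p["u", "v"], ct$p.value, tolerance = 1e-10)

  # constant columns are reported missing
  m4 <- spearman_matrix(cbind(a = 1:8, c = rep(2, 8)))
  expect_true(is.na(m4$rho["a", "c"]))
})

test_that("ddct_fold_change: identity, one-cycle shift, control mean", {
  base <- expand.grid(rep = 1:3, gene = c("Ocln", "Gapdh"),
                      sample_id = paste0("s", 1:6))
  base$group <- rep(c("control", "treated"), each = 9)[seq_len(nrow(base))]
  base$group <- ifelse(as.integer(sub("s", "", base$sample_id)) <= 3,
                       "control", "treated")
  base$ct <- 24
  same <- ddct_fold_change(base, "Ocln", "Gapdh", "control")
  expect_true(all(same$fold_change == 1))

  shift <- base
  shift$ct[shift$gene == "Ocln" & shift$group == "treated"] <- 23
  fc <- ddct_fold_change(shift, "Ocln", "Gapdh", "control")
  expect_equal(fc$fold_change[fc$group == "treated"], rep(2, 3))
  expect_equal(mean(fc$fold_change[fc$group == "control"]), 1)

  expect_error(ddct_fold_change(base, "Ocln", "Actb", "control"),
               "missing reference")
  bad <- base; bad$ct[1] <- -2
  expect_error(ddct_fold_change(bad, "Ocln", "Gapdh", "control"), "positive")
})

test_that("welch type-I error is calibrated at the 5 percent level", {
  set.seed(2024)
  reps <- 10000; n <- 10
  xm <- matrix(rnorm(n * reps), n)
  ym <- matrix(rnorm(n * reps), n)
  # vectorized closed-form Welch p-values
  mx <- colMeans(xm); my <- colMeans(ym)
  vx <- colSums((xm - rep(mx, each = n))^2) / (n - 1)
  vy <- colSums((ym - rep(my, each = n))^2) / (n - 1)
  tt <- (mx - my) / sqrt(vx / n + vy / n)
  df <- (vx / n + vy / n)^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
  pv <- 2 * pt(-abs(tt), df)
  rate <- mean(pv < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
  # spot check the vectorized oracle against the package implementation
  for (i in c(1, 500, 9999))
    expect_equal(welch_t(xm[, i], ym[, i])$p, pv[i], tolerance = 1e-12)
})
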