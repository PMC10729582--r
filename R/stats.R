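# The study's statistical layer: Shapiro-Wilk screening, Welch t, two-way
# ANOVA with Holm-Sidak step-down post hoc, Spearman correlation matrices
# and 2^-ddCt relative quantification.

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return data frame: `test`, `statistic` (W), `p`.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 observations")
  if (sd(values) == 0) stop("zero variance: normality is undefined")
  s <- shapiro.test(values)
  data.frame(test = "shapiro-wilk", statistic = unname(s$statistic),
             p = s$p.value)
}

#' Welch two-sample t-test
#'
#' Two-tailed t-test with Welch's correction for unequal variances
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return data frame: `test`, `statistic`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(data.frame(test = "welch-t", statistic = 0, df = NA_real_,
                        p = 1, mean_x = mean(x), mean_y = mean(y)))
    }
    stop("zero variance in both groups")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  data.frame(test = "welch-t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             mean_x = mean(x), mean_y = mean(y))
}

#' Holm-Sidak step-down adjustment
#'
#' Raw p-values are sorted ascending; the i-th smallest is adjusted to
#' `1 - (1 - p_(i))^(m - i + 1)`, enforced monotone by a running maximum and
#' capped at 1. Returned in the input order.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order as `p`.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-way ANOVA with Holm-Sidak post hoc comparisons
#'
#' Fits `value ~ group * age` with sum-to-zero contrasts and reports
#' partial (type III) F-tests for both main effects and the interaction,
#' followed by pairwise comparisons of the group-by-age cell means using
#' the pooled residual variance, adjusted by [holm_sidak()].
#'
#' @param values numeric response.
#' @param group,age categorical factors (>= 2 levels each).
#' @param posthoc which pairwise cell comparisons form the family:
#'   `"within-age"` (hypertensive vs control at each age, and ages within
#'   each group; the comparisons shown in the figures) or `"all"`.
#' @return list: `anova` (data frame with `effect`, `df`, `F`, `p`) and
#'   `posthoc` (data frame with `comparison`, `estimate`, `t`, `df`,
#'   `p_raw`, `p_adj`).
#' @export
anova2_holm_sidak <- function(values, group, age,
                              posthoc = c("within-age", "all")) {
  posthoc <- match.arg(posthoc)
  group <- factor(group); age <- factor(age)
  if (nlevels(group) < 2 || nlevels(age) < 2)
    stop("both factors need at least 2 levels")
  dat <- data.frame(value = values, group = group, age = age)
  fit <- lm(value ~ group * age, data = dat,
            contrasts = list(group = "contr.sum", age = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  rows <- c("group", "age", "group:age")
  anova_tab <- data.frame(effect = rows,
                          df = a3[rows, "Df"],
                          F = a3[rows, "F value"],
                          p = a3[rows, "Pr(>F)"])
  # pairwise cell-mean comparisons on the pooled residual variance
  cells <- aggregate(value ~ group + age, data = dat,
                     FUN = function(v) c(m = mean(v), n = length(v)))
  cm <- data.frame(group = cells$group, age = cells$age,
                   mean = cells$value[, "m"], n = cells$value[, "n"])
  mse <- sum(fit$residuals^2) / fit$df.residual
  pairs <- utils::combn(nrow(cm), 2)
  keep <- logical(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    same_age <- cm$age[i1] == cm$age[i2]
    same_group <- cm$group[i1] == cm$group[i2]
    keep[j] <- if (posthoc == "all") TRUE else (same_age || same_group)
  }
  pairs <- pairs[, keep, drop = FALSE]
  ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- cm$mean[i1] - cm$mean[i2]
    se <- sqrt(mse * (1 / cm$n[i1] + 1 / cm$n[i2]))
    tval <- est / se
    data.frame(comparison = paste0(cm$group[i1], ":", cm$age[i1], " - ",
                                   cm$group[i2], ":", cm$age[i2]),
               estimate = est, t = tval, df = fit$df.residual,
               p_raw = 2 * pt(-abs(tval), fit$df.residual))
  }))
  ph$p_adj <- holm_sidak(ph$p_raw)
  list(anova = anova_tab, posthoc = ph)
}

#' Spearman correlation matrix
#'
#' Average-rank Spearman correlation for every pair of columns. Two-sided
#' p-values use the t-approximation for n > 10 and the exact permutation
#' distribution for n <= 10. Pairs involving a constant column are reported
#' as missing.
#'
#' @param x data frame or matrix (columns = variables, rows = paired
#'   observations).
#' @param y optional second block of columns; defaults to `x` (square,
#'   symmetric output).
#' @return list of matrices `rho` and `p`.
#' @export
spearman_matrix <- function(x, y = NULL) {
  x <- as.matrix(x)
  symmetric <- is.null(y)
  y <- if (symmetric) x else as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  rho <- matrix(NA_real_, ncol(x), ncol(y),
                dimnames = list(colnames(x), colnames(y)))
  p <- rho
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(y))) {
      if (symmetric && j < i) { rho[i, j] <- rho[j, i]; p[i, j] <- p[j, i]; next }
      ok <- is.finite(x[, i]) & is.finite(y[, j])
      n <- sum(ok)
      if (n < 4) next
      xv <- x[ok, i]; yv <- y[ok, j]
      if (sd(xv) == 0 || sd(yv) == 0) next
      rx <- rank(xv); ry <- rank(yv)
      r <- cor(rx, ry)
      rho[i, j] <- r
      if (symmetric && i == j) { p[i, j] <- NA_real_; next }
      if (n <= 10) {
        p[i, j] <- spearman_exact_pval_cpp(rx, ry)
      } else {
        tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
        p[i, j] <- 2 * pt(-abs(tval), n - 2)
      }
    }
  }
  list(rho = rho, p = p)
}

#' Relative quantification by the comparative 2^-ddCt method
#'
#' Per sample: dCt = mean Ct(target) - mean Ct(reference) over replicates;
#' ddCt = dCt - mean dCt of the control group; fold change = 2^-ddCt.
#'
#' @param qpcr data frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (one row per replicate).
#' @param target target gene name.
#' @param reference reference (housekeeping) gene name, e.g. `"Gapdh"`.
#' @param control_group group level used for normalization.
#' @return data frame: `sample_id`, `group`, `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(qpcr, target, reference, control_group) {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(qpcr)))
  if (!all(is.finite(qpcr$ct)) || any(qpcr$ct <= 0))
    stop("Ct values must be finite and positive")
  if (!reference %in% qpcr$gene) stop("missing reference gene: ", reference)
  if (!target %in% qpcr$gene) stop("missing target gene: ", target)
  samples <- unique(qpcr[, c("sample_id", "group")])
  dct <- vapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample_id[i]
    tg <- qpcr$ct[qpcr$sample_id == s & qpcr$gene == target]
    rf <- qpcr$ct[qpcr$sample_id == s & qpcr$gene == reference]
    if (length(tg) == 0 || length(rf) == 0)
      stop("sample ", s, " lacks target or reference replicates")
    mean(tg) - mean(rf)
  }, numeric(1))
  ctrl <- samples$group == control_group
  if (!any(ctrl)) stop("no samples in control group: ", control_group)
  ddct <- dct - mean(dct[ctrl])
  data.frame(sample_id = samples$sample_id, group = samples$group,
             dct = dct, ddct = ddct, fold_change = 2^(-ddct))
}
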