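#' Hedges' g standardised effect size
#'
#' Bias-corrected standardised mean difference,
#' `g = J (mean2 - mean1) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 df - 1)`, `df = n1 + n2 - 2`. The sign convention is
#' group 2 minus group 1.
#'
#' @param group1,group2 Numeric vectors (each n >= 2).
#' @return Hedges' g.
#' @export
hedges_g <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) / df
  if (sp2 <= 0) {
    if (mean(group2) == mean(group1)) return(0)
    stop("pooled standard deviation is zero: effect size undefined")
  }
  j <- 1 - 3 / (4 * df - 1)
  j * (mean(group2) - mean(group1)) / sqrt(sp2)
}

#' Bootstrap confidence interval for Hedges' g
#'
#' Stratified resampling within each group; the percentile interval of the
#' resampled effect-size distribution (BCa optional). Resamples with zero
#' pooled variance are redrawn (their count is reported). A CI excluding
#' zero is flagged significant.
#'
#' @param group1,group2 Numeric vectors.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param conf Confidence level.
#' @param method `"percentile"` (default) or `"bca"`.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `effect`, `ci_low`, `ci_high`, `significant`, `n_boot`,
#'   `n_redrawn`, `method`.
#' @export
bootstrap_ci <- function(group1, group2, n_boot = 5000, conf = 0.95,
                         method = c("percentile", "bca"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(group1); n2 <- length(group2)
  obs <- hedges_g(group1, group2)

  boot_g <- function(k) {
    i1 <- matrix(sample.int(n1, k * n1, replace = TRUE), nrow = n1)
    i2 <- matrix(sample.int(n2, k * n2, replace = TRUE), nrow = n2)
    x1 <- matrix(group1[i1], nrow = n1)
    x2 <- matrix(group2[i2], nrow = n2)
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    v1 <- (colMeans(x1^2) - m1^2) * n1 / (n1 - 1)
    v2 <- (colMeans(x2^2) - m2^2) * n2 / (n2 - 1)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    j <- 1 - 3 / (4 * df - 1)
    ifelse(sp2 > 0, j * (m2 - m1) / sqrt(sp2), NA_real_)
  }
  g <- boot_g(n_boot)
  n_redrawn <- 0L
  while (anyNA(g)) {
    bad <- which(is.na(g))
    n_redrawn <- n_redrawn + length(bad)
    g[bad] <- boot_g(length(bad))
    if (n_redrawn > 100 * n_boot) stop("degenerate groups: resampling cannot proceed")
  }
  alpha <- 1 - conf
  if (method == "percentile") {
    ci <- unname(stats::quantile(g, c(alpha / 2, 1 - alpha / 2), type = 7))
  } else {
    z0 <- stats::qnorm(mean(g < obs))
    ## jackknife acceleration over both groups
    th <- c(
      vapply(seq_len(n1), function(i) hedges_g(group1[-i], group2), numeric(1)),
      vapply(seq_len(n2), function(i) hedges_g(group1, group2[-i]), numeric(1)))
    u <- mean(th) - th
    a <- sum(u^3) / (6 * sum(u^2)^1.5)
    zl <- stats::qnorm(alpha / 2); zu <- stats::qnorm(1 - alpha / 2)
    p1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    ci <- unname(stats::quantile(g, c(p1, p2), type = 7))
  }
  list(effect = obs, ci_low = ci[1], ci_high = ci[2],
       significant = ci[1] > 0 || ci[2] < 0,
       n_boot = n_boot, n_redrawn = n_redrawn, method = method)
}

#' Block permutation test with colony as the exchangeable unit
#'
#' Transparent surrogate for a mixed-effects permutational analysis: the
#' group label (e.g. depth) is a property of the colony, so labels are
#' permuted across whole blocks (colonies), never within, and the test
#' statistic (difference of group medians by default) is recomputed for each
#' permutation. `p = (1 + #{|T*| >= |T|}) / (n_perm + 1)`.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation (2 levels).
#' @param blocks Block (colony) id per observation; every block must carry a
#'   single group label.
#' @param n_perm Number of permutations (default 999).
#' @param statistic Function of `(values, groups)` returning a scalar;
#'   default difference of group medians (level 2 minus level 1).
#' @param seed Optional integer seed.
#' @return List with `p_value`, `observed`, `n_perm`.
#' @export
permutation_test <- function(values, groups, blocks, n_perm = 999,
                             statistic = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("exactly 2 group levels are required")
  groups <- droplevels(groups)
  blocks <- as.character(blocks)
  block_group <- tapply(as.integer(groups), blocks, function(x) {
    u <- unique(x)
    if (length(u) != 1) stop("a block carries more than one group label")
    u
  })
  if (min(table(block_group)) < 2)
    stop("need at least 2 blocks per group")
  if (is.null(statistic)) {
    lev <- levels(groups)
    statistic <- function(v, gr)
      stats::median(v[gr == lev[2]]) - stats::median(v[gr == lev[1]])
  }
  obs <- statistic(values, groups)
  bnames <- names(block_group)
  bg <- as.integer(block_group)
  block_of <- match(blocks, bnames)
  tstar <- numeric(n_perm)
  lev <- levels(groups)
  for (p in seq_len(n_perm)) {
    perm_bg <- sample(bg)
    gr <- factor(lev[perm_bg[block_of]], levels = lev)
    tstar[p] <- statistic(values, gr)
  }
  p_val <- (1 + sum(abs(tstar) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(p_value = p_val, observed = obs, n_perm = n_perm)
}

#' Two-group comparison report
#'
#' Bundles [hedges_g()], [bootstrap_ci()] and [permutation_test()] into one
#' record per metric, the way depth contrasts are reported (effect size with
#' bootstrap CI, block-permutation p-value).
#'
#' @param data Data frame with columns `value`, `group`, `block`.
#' @param n_boot,n_perm Resampling sizes.
#' @param seed Optional seed.
#' @return A `group_comparison` list.
#' @export
compare_groups <- function(data, n_boot = 5000, n_perm = 999, seed = NULL) {
  stopifnot(all(c("value", "group", "block") %in% names(data)))
  g <- as.factor(data$group)
  lev <- levels(droplevels(g))
  v1 <- data$value[g == lev[1]]
  v2 <- data$value[g == lev[2]]
  ci <- bootstrap_ci(v1, v2, n_boot = n_boot, seed = seed)
  pt <- permutation_test(data$value, g, data$block, n_perm = n_perm)
  structure(list(group_levels = lev, n1 = length(v1), n2 = length(v2),
                 effect = ci$effect, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 significant = ci$significant,
                 p_perm = pt$p_value, n_boot = n_boot, n_perm = n_perm),
            class = "group_comparison")
}
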