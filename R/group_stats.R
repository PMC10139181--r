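#' Dunn's post-hoc pairwise rank test
#'
#' Pairwise z statistics on Kruskal-Wallis ranks with tie correction:
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups. P-values are two-sided
#' normal, adjusted for the number of pairwise comparisons.
#'
#' @param x numeric values.
#' @param g grouping factor.
#' @param p_adjust_method multiplicity adjustment (default "bonferroni").
#' @return data.frame: group_a, group_b, z, p_value, p_adj.
#' @export
dunn_test <- function(x, g, p_adjust_method = "bonferroni") {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("dunn_test needs at least two groups")
  r <- rank(x)
  N <- length(x)
  tie_tab <- table(x)
  TT <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- combn(levels(g), 2)
  res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - TT) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[b]] - rbar[[a]]) / se
    data.frame(group_a = a, group_b = b, z = z,
               p_value = 2 * pnorm(-abs(z)))
  }))
  res$p_adj <- p.adjust(res$p_value, method = p_adjust_method)
  rownames(res) <- NULL
  res
}

#' Descriptive statistics over a feature methylation profile
#'
#' Given per-feature per-sample methylation percentages and a sample-to-group
#' map, computes: Shapiro-Wilk normality per feature; pairwise two-sample t
#' statistics between groups per feature; one-way ANOVA across features
#' (pooling samples); and, per feature, Kruskal-Wallis across groups followed
#' by Dunn pairwise z with multiplicity-adjusted p.
#'
#' @param profile data.frame from [feature_methylation_profile()] (columns
#'   feature, sample, meth_pct).
#' @param groups named character vector mapping sample to group.
#' @return list with `shapiro`, `t_tests`, `anova`, `kruskal`, `dunn`.
#' @export
group_stats <- function(profile, groups) {
  d <- profile[!is.na(profile$meth_pct), ]
  d$group <- groups[d$sample]
  if (any(is.na(d$group))) stop("profile contains samples absent from 'groups'")

  shapiro <- do.call(rbind, lapply(split(d, d$feature), function(f) {
    if (nrow(f) < 3L || stats::sd(f$meth_pct) == 0) {
      warning(sprintf("feature %s: <3 observations or no variance, normality test skipped",
                      f$feature[1]), call. = FALSE)
      return(data.frame(feature = f$feature[1], W = NA_real_, p_value = NA_real_))
    }
    sw <- shapiro.test(f$meth_pct)
    data.frame(feature = f$feature[1], W = unname(sw$statistic),
               p_value = sw$p.value)
  }))

  glv <- unique(d$group)
  gpairs <- if (length(glv) > 1) combn(glv, 2) else matrix(character(0), 2)
  t_tests <- do.call(rbind, lapply(split(d, d$feature), function(f) {
    do.call(rbind, lapply(seq_len(ncol(gpairs)), function(k) {
      xa <- f$meth_pct[f$group == gpairs[1, k]]
      xb <- f$meth_pct[f$group == gpairs[2, k]]
      if (length(xa) < 2 || length(xb) < 2 ||
          (stats::sd(xa) == 0 && stats::sd(xb) == 0))
        return(data.frame(feature = f$feature[1], group_a = gpairs[1, k],
                          group_b = gpairs[2, k], t = NA_real_,
                          p_value = NA_real_))
      tt <- t.test(xa, xb)
      data.frame(feature = f$feature[1], group_a = gpairs[1, k],
                 group_b = gpairs[2, k], t = unname(tt$statistic),
                 p_value = tt$p.value)
    }))
  }))
  rownames(t_tests) <- NULL

  anova_fit <- aov(meth_pct ~ feature, data = d)
  an <- summary(anova_fit)[[1]]
  anova <- data.frame(F = an$`F value`[1], p_value = an$`Pr(>F)`[1])

  kruskal <- do.call(rbind, lapply(split(d, d$feature), function(f) {
    if (length(unique(f$group)) < 2L)
      return(data.frame(feature = f$feature[1], statistic = NA_real_,
                        p_value = NA_real_))
    kw <- kruskal.test(f$meth_pct, factor(f$group))
    data.frame(feature = f$feature[1], statistic = unname(kw$statistic),
               p_value = kw$p.value)
  }))

  dunn <- do.call(rbind, lapply(split(d, d$feature), function(f) {
    if (length(unique(f$group)) < 2L) return(NULL)
    res <- dunn_test(f$meth_pct, f$group)
    cbind(feature = f$feature[1], res)
  }))
  rownames(dunn) <- NULL

  list(shapiro = shapiro, t_tests = t_tests, anova = anova, kruskal = kruskal,
       dunn = dunn)
}
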