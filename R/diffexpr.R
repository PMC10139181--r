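#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of count / geometric-mean count, taken
#' over genes with a nonzero geometric mean, rescaled so the factors have
#' geometric mean 1.
#'
#' @param counts integer matrix genes x samples.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  lgm <- rowMeans(log(counts))
  use <- is.finite(lgm)
  if (!any(use)) stop("no gene with all-positive counts; cannot normalise")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - lgm[use])))
  sf / exp(mean(log(sf)))
}

#' Per-gene shrunk negative-binomial dispersion
#'
#' Method-of-moments dispersion from normalised counts (pooled within-group
#' variance), shrunk on the log scale toward a smooth mean-dispersion trend
#' fitted by lowess on genes with a positive raw estimate. Clipped to
#' [1e-8, 10].
#'
#' @param counts integer matrix genes x samples.
#' @param factors size factors (default [size_factors()]).
#' @param groups character vector of group labels per column (default: one
#'   group).
#' @param prior_df weight of the trend in the shrinkage (default 4 residual
#'   degrees of freedom).
#' @return numeric vector of shrunk dispersions alpha-tilde with attribute
#'   `trend` (per-gene trend values).
#' @export
estimate_nb_dispersion <- function(counts, factors = size_factors(counts),
                                   groups = rep("all", ncol(counts)),
                                   prior_df = 4) {
  y <- sweep(counts, 2, factors, "/")
  G <- length(unique(groups))
  n <- ncol(counts)
  if (n - G < 1L) stop("need at least one residual degree of freedom")
  mu <- rowMeans(y)
  ss <- rep(0, nrow(y))
  for (g in unique(groups)) {
    cols <- groups == g
    yg <- y[, cols, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
  }
  s2 <- ss / (n - G)
  shot <- mu * mean(1 / factors)  # Poisson part of the NB variance
  raw <- (s2 - shot) / mu^2
  raw[!is.finite(raw)] <- NA_real_
  lo <- 1e-8; hi <- 10
  pos <- !is.na(raw) & raw > 1e-6 & mu > 0
  trend <- rep(NA_real_, nrow(y))
  if (sum(pos) >= 10) {
    fit <- lowess(log(mu[pos]), log(raw[pos]), f = 0.5)
    trend <- exp(approx(fit$x, fit$y, xout = log(pmax(mu, min(mu[pos]))),
                        rule = 2, ties = "ordered")$y)
  } else if (any(pos)) {
    trend <- rep(median(raw[pos]), nrow(y))
  } else {
    trend <- rep(lo, nrow(y))
  }
  # blend on the natural scale: a log-scale (geometric) blend is biased low,
  # which makes the downstream Wald test anticonservative
  w <- n - G
  raw_filled <- ifelse(is.na(raw) | raw <= 0, trend / 10, raw)
  out <- clip((w * clip(raw_filled, lo, hi) + prior_df * clip(trend, lo, hi)) /
                (w + prior_df), lo, hi)
  out[s2 == 0 & mu > 0] <- lo  # literally no replicate variance
  attr(out, "trend") <- trend
  out
}

#' Negative-binomial Wald test between two groups
#'
#' log2FC = log2((qA + pseudo) / (qB + pseudo)) with q the group means of
#' normalised counts; its standard error comes from the delta-method
#' negative-binomial variance of each group mean; two-sided normal p. Genes
#' with all-zero counts are excluded from testing (NA statistics) and do not
#' count toward the Bonferroni denominator.
#'
#' @param counts integer matrix genes x samples.
#' @param groups character vector of group labels per column.
#' @param contrast character pair c(group_a, group_b); log2FC is A over B.
#' @param factors size factors (default computed from the contrast's columns).
#' @param dispersion per-gene dispersions (default estimated and shrunk).
#' @param pseudo pseudo-count added to the normalised group means (default 0.5).
#' @return data.frame of class `de_result`: gene_id, base_mean, log2fc,
#'   se_log2fc, wald_stat, p_value; attribute `contrast`.
#' @export
nb_wald_test <- function(counts, groups, contrast, factors = NULL,
                         dispersion = NULL, pseudo = 0.5) {
  stopifnot(length(contrast) == 2L, all(contrast %in% groups))
  cols <- groups %in% contrast
  counts <- counts[, cols, drop = FALSE]
  groups <- groups[cols]
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersion))
    dispersion <- estimate_nb_dispersion(counts, factors, groups)
  y <- sweep(counts, 2, factors, "/")
  a <- groups == contrast[1]; b <- groups == contrast[2]
  qa <- rowMeans(y[, a, drop = FALSE]); qb <- rowMeans(y[, b, drop = FALSE])
  log2fc <- log2((qa + pseudo) / (qb + pseudo))
  var_q <- function(q, cols_g) {
    qf <- pmax(q, pseudo)  # floor so all-zero groups keep a finite variance
    sapply(seq_along(q), function(i)
      sum(qf[i] / factors[cols_g] + dispersion[i] * qf[i]^2)) /
      sum(cols_g)^2
  }
  va <- var_q(qa, a); vb <- var_q(qb, b)
  se <- sqrt(va / ((qa + pseudo) * log(2))^2 + vb / ((qb + pseudo) * log(2))^2)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))
  allzero <- rowSums(counts) == 0
  log2fc[allzero] <- NA_real_; se[allzero] <- NA_real_
  wald[allzero] <- NA_real_; p[allzero] <- NA_real_
  out <- data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    base_mean = rowMeans(y), log2fc = log2fc, se_log2fc = se,
                    wald_stat = wald, p_value = p)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Flag differentially expressed genes
#'
#' Bonferroni-adjusts p over tested genes and flags is_deg = (p_adj < alpha
#' and |log2FC| > lfc).
#'
#' @param results a `de_result` data.frame.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @return the input with p_adj and is_deg appended; attribute `counts` gives
#'   per-direction DEG counts.
#' @export
call_degs <- function(results, alpha = 0.05, lfc = 1.0) {
  tested <- !is.na(results$p_value)
  G <- sum(tested)
  p_adj <- rep(NA_real_, nrow(results))
  p_adj[tested] <- pmin(1, results$p_value[tested] * G)
  out <- results
  out$p_adj <- p_adj
  out$is_deg <- tested & p_adj < alpha & abs(results$log2fc) > lfc
  attr(out, "contrast") <- attr(results, "contrast")
  attr(out, "counts") <- c(up = sum(out$is_deg & out$log2fc > 0, na.rm = TRUE),
                           down = sum(out$is_deg & out$log2fc < 0, na.rm = TRUE))
  class(out) <- c("de_result", "data.frame")
  out
}

#' Two-group differential expression, end to end
#'
#' Convenience wrapper: size factors, shrunk dispersions, NB Wald test and
#' DEG flagging under the Bonferroni + fold-change rule.
#'
#' @inheritParams nb_wald_test
#' @inheritParams call_degs
#' @return a `de_result` with p_adj and is_deg.
#' @export
de_test <- function(counts, groups, contrast, alpha = 0.05, lfc = 1.0,
                    pseudo = 0.5) {
  call_degs(nb_wald_test(counts, groups, contrast, pseudo = pseudo),
            alpha = alpha, lfc = lfc)
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Differential expression (%s vs %s): %d genes tested\n",
              ct[1], ct[2], sum(!is.na(x$p_value))))
  if (!is.null(x$is_deg)) {
    cnt <- attr(x, "counts")
    cat(sprintf("  %d DEGs (%d higher at %s, %d higher at %s)\n",
                sum(x$is_deg), cnt["up"], ct[1], cnt["down"], ct[2]))
  }
  invisible(x)
}
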