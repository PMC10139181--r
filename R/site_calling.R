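#' One-tailed binomial test for excess methylation at a site
#'
#' Tests H0: a read is methylated with probability p0 = 0.5 against excess
#' methylation, returning the exact upper tail P(X >= m | n = m + u, p0).
#' Methylated sites should reject: under complete bisulfite conversion an
#' unmethylated site yields methylated reads only by chance.
#'
#' @param m,u methylated and unmethylated read counts (vectorised).
#' @param p0 null methylation probability (default 0.5).
#' @return p-values in [0, 1].
#' @examples
#' binomial_site_test(5, 0) # 0.5^5
#' binomial_site_test(8, 2) # sum_{k>=8} C(10,k)/2^10
#' @export
binomial_site_test <- function(m, u, p0 = 0.5) {
  if (length(m) != length(u)) stop("m and u must have equal length")
  if (any(m < 0 | u < 0)) stop("counts must be non-negative")
  n <- m + u
  if (any(n == 0)) stop("binomial test undefined at zero depth")
  pbinom(m - 1, n, p0, lower.tail = FALSE)
}

#' Call true methylated sites in one sample
#'
#' Applies the binomial excess-methylation test to every site with depth >=
#' `min_depth`, corrects with Benjamini-Hochberg within the sample, and calls
#' a site true-methylated when depth >= `min_depth` and q <= `fdr`. Sites
#' below the depth threshold are never tested nor called; their p and q are NA.
#'
#' @param sites cytosine-report data.frame (see [read_cytosine_report()]).
#' @param min_depth minimum depth for testing (default 5).
#' @param fdr Benjamini-Hochberg q-value threshold (default 0.01).
#' @param p0 null methylation probability (default 0.5); a conversion-based
#'   null can be supplied instead.
#' @return the input with columns p_value, q_value, meth_fraction,
#'   is_true_methylated appended; class `site_calls`.
#' @export
call_true_methylated <- function(sites, min_depth = 5L, fdr = 0.01, p0 = 0.5) {
  depth <- sites$count_methylated + sites$count_unmethylated
  tested <- depth >= min_depth
  p <- rep(NA_real_, nrow(sites))
  q <- rep(NA_real_, nrow(sites))
  if (any(tested)) {
    p[tested] <- binomial_site_test(sites$count_methylated[tested],
                                    sites$count_unmethylated[tested], p0 = p0)
    q[tested] <- p.adjust(p[tested], method = "BH")
  }
  out <- sites
  out$depth <- depth
  out$p_value <- p
  out$q_value <- q
  out$meth_fraction <- ifelse(depth > 0, sites$count_methylated / depth, NA_real_)
  out$is_true_methylated <- tested & !is.na(q) & q <= fdr
  attr(out, "min_depth") <- min_depth
  attr(out, "fdr") <- fdr
  attr(out, "p0") <- p0
  attr(out, "correction_scope") <- "per sample, contexts pooled"
  class(out) <- c("site_calls", "data.frame")
  out
}

#' Bisulfite conversion rate from spike-in control sites
#'
#' The control chromosome carries only unmethylated cytosines, so its
#' conversion rate is 100 * sum(unmethylated) / sum(depth).
#'
#' @param control_sites cytosine-report rows from the control chromosome.
#' @return percentage in [0, 100].
#' @export
conversion_rate <- function(control_sites) {
  if (nrow(control_sites) == 0L) stop("no control sites supplied")
  tot <- sum(control_sites$count_methylated) + sum(control_sites$count_unmethylated)
  if (tot == 0) stop("control sites have zero total depth")
  100 * sum(control_sites$count_unmethylated) / tot
}

#' Context breakdown of called methylated cytosines
#'
#' @param calls a `site_calls` object.
#' @return named fractions over CG, CHG, CHH summing to 1.
#' @export
context_breakdown <- function(calls) {
  called <- calls[calls$is_true_methylated, ]
  if (nrow(called) == 0L)
    return(c(CG = NA_real_, CHG = NA_real_, CHH = NA_real_))
  tab <- table(factor(called$context, levels = c("CG", "CHG", "CHH")))
  as.vector(tab) / sum(tab) -> fr
  setNames(fr, c("CG", "CHG", "CHH"))
}

#' Sample-level methylation summaries
#'
#' Per-chromosome counts of called methylated cytosines per sample, an OLS
#' regression of per-chromosome mC count on chromosome size (slope, R-squared,
#' p), and pairwise Pearson correlations of methylation fractions over sites
#' called in both members of each sample pair. Chromosomes absent from
#' `chrom_sizes` (e.g. the spike-in control) are excluded.
#'
#' @param calls_list named list of `site_calls`, one per sample.
#' @param chrom_sizes named vector of chromosome sizes.
#' @return list with `per_chrom` (chrom x sample count matrix), `regression`
#'   (per sample: slope, r_squared, p_value), and `pearson` (per sample pair:
#'   r, p_value, n_shared).
#' @export
sample_summaries <- function(calls_list, chrom_sizes) {
  stopifnot(is.list(calls_list), length(calls_list) >= 1L)
  chroms <- names(chrom_sizes)
  per_chrom <- sapply(calls_list, function(cl) {
    cl <- cl[cl$is_true_methylated & cl$chrom %in% chroms, ]
    table(factor(cl$chrom, levels = chroms))
  })
  per_chrom <- matrix(per_chrom, nrow = length(chroms),
                      dimnames = list(chroms, names(calls_list)))
  regression <- do.call(rbind, lapply(colnames(per_chrom), function(s) {
    fit <- lm(per_chrom[, s] ~ unname(chrom_sizes))
    sm <- summary(fit)
    pv <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
    data.frame(sample = s, slope = unname(coef(fit)[2]),
               r_squared = sm$r.squared, p_value = pv)
  }))
  pairs <- if (length(calls_list) > 1) combn(names(calls_list), 2) else
    matrix(character(0), nrow = 2)
  pearson <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- calls_list[[pairs[1, k]]]; b <- calls_list[[pairs[2, k]]]
    a <- a[a$is_true_methylated & a$chrom %in% chroms, ]
    b <- b[b$is_true_methylated & b$chrom %in% chroms, ]
    key_a <- paste(a$chrom, a$pos, a$strand)
    key_b <- paste(b$chrom, b$pos, b$strand)
    shared <- intersect(key_a, key_b)
    if (length(shared) < 3)
      return(data.frame(sample_a = pairs[1, k], sample_b = pairs[2, k],
                        r = NA_real_, p_value = NA_real_,
                        n_shared = length(shared)))
    xa <- a$meth_fraction[match(shared, key_a)]
    xb <- b$meth_fraction[match(shared, key_b)]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
      return(data.frame(sample_a = pairs[1, k], sample_b = pairs[2, k],
                        r = NA_real_, p_value = NA_real_,
                        n_shared = length(shared)))
    ct <- cor.test(xa, xb)
    data.frame(sample_a = pairs[1, k], sample_b = pairs[2, k],
               r = unname(ct$estimate), p_value = ct$p.value,
               n_shared = length(shared))
  }))
  list(per_chrom = per_chrom, regression = regression, pearson = pearson)
}

#' @export
print.site_calls <- function(x, ...) {
  cat("Site calls:", nrow(x), "sites;",
      sum(x$depth >= attr(x, "min_depth")), "tested (depth >=",
      attr(x, "min_depth"), ");", sum(x$is_true_methylated),
      "called true-methylated at FDR", attr(x, "fdr"), "\n")
  invisible(x)
}

#' @export
summary.site_calls <- function(object, ...) {
  br <- context_breakdown(object)
  cat("called mC context fractions: CG", round(br["CG"], 4),
      "CHG", round(br["CHG"], 4), "CHH", round(br["CHH"], 4), "\n")
  invisible(br)
}
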