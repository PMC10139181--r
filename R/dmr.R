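#' Assemble per-sample cytosine reports into count matrices
#'
#' Intersects sites (chrom, pos, strand, context) across samples and returns
#' methylated-count and depth matrices. The spike-in control chromosome is
#' dropped.
#'
#' @param reports named list of cytosine-report data.frames or file paths.
#' @param control_chrom chromosome to exclude (default "lambda").
#' @return list: `sites` (data.frame chrom, pos, strand, context), `M`, `N`
#'   (sites x samples matrices).
#' @export
assemble_bs_counts <- function(reports, control_chrom = "lambda") {
  stopifnot(length(reports) >= 2L, !is.null(names(reports)))
  reports <- lapply(reports, function(r)
    if (is.character(r)) read_cytosine_report(r) else r)
  reports <- lapply(reports, function(r) r[r$chrom != control_chrom, ])
  keys <- lapply(reports, function(r) paste(r$chrom, r$pos, r$strand, r$context))
  common <- Reduce(intersect, keys)
  idx <- lapply(keys, match, x = common)
  r1 <- reports[[1]][idx[[1]], ]
  sites <- data.frame(chrom = r1$chrom, pos = r1$pos, strand = r1$strand,
                      context = r1$context)
  M <- sapply(seq_along(reports), function(i)
    reports[[i]]$count_methylated[idx[[i]]])
  U <- sapply(seq_along(reports), function(i)
    reports[[i]]$count_unmethylated[idx[[i]]])
  M <- matrix(M, ncol = length(reports), dimnames = list(NULL, names(reports)))
  N <- matrix(M + U, ncol = length(reports), dimnames = list(NULL, names(reports)))
  ord <- order(sites$chrom, sites$context, sites$pos)
  list(sites = sites[ord, ], M = M[ord, , drop = FALSE], N = N[ord, , drop = FALSE])
}

#' Coverage-weighted moving-average smoothing of methylation
#'
#' For each site, the coverage-weighted mean methylation fraction over all
#' sites within +/- window/2 bp on the same chromosome (and context stream).
#' Isolated sites are returned unchanged (their window contains only
#' themselves).
#'
#' @param pos sorted positions within one chromosome/context stream.
#' @param m,n methylated counts and depths (vectors, pooled over samples).
#' @param window full window width in bp (default 500).
#' @return list: `smoothed` fractions, `sm`, `sn` window sums of m and n.
#' @export
smooth_methylation <- function(pos, m, n, window = 500L) {
  half <- window / 2
  sm <- window_sum(pos, m, half)
  sn <- window_sum(pos, n, half)
  list(smoothed = ifelse(sn > 0, sm / sn, NA_real_), sm = sm, sn = sn)
}

#' Shrunk per-site beta-binomial dispersion
#'
#' Method-of-moments dispersion per site from replicate variation within each
#' group, shrunk toward the genome-wide mean dispersion with a weight
#' proportional to the site's total depth (shallow sites take the prior, deep
#' sites keep more of their own estimate). Sites where no method-of-moments
#' estimate exists (insufficient replication or a non-positive estimate) take
#' the prior exactly. Estimates are clipped to [1e-6, 0.999].
#'
#' @param M,N methylated-count and depth matrices (sites x samples).
#' @param groups character vector of group labels, one per column.
#' @return numeric vector of shrunk dispersions, with attribute
#'   `prior` (the genome-wide prior on the natural scale).
#' @export
estimate_dispersion <- function(M, N, groups) {
  lo <- 1e-6; hi <- 0.999
  numer <- rep(0, nrow(M)); denom <- rep(0, nrow(M)); kdf <- rep(0, nrow(M))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) next
    Mg <- M[, cols, drop = FALSE]; Ng <- N[, cols, drop = FALSE]
    used <- Ng > 0
    k <- rowSums(used)
    sm <- rowSums(Mg); sn <- rowSums(Ng)
    phat <- ifelse(sn > 0, sm / sn, NA_real_)
    ptil <- (sm + 0.5) / (sn + 1)
    P <- ifelse(Ng > 0, Mg / Ng, 0)
    S <- rowSums(Ng * (P - phat)^2)
    contrib_ok <- k >= 2 & sn > 0
    numer <- numer + ifelse(contrib_ok, S / (ptil * (1 - ptil)) - (k - 1), 0)
    denom <- denom + ifelse(contrib_ok, rowSums(pmax(Ng - 1, 0) * used), 0)
    kdf <- kdf + ifelse(contrib_ok, k - 1, 0)
  }
  raw <- ifelse(denom > 0 & kdf > 0, numer / denom, NA_real_)
  # per-site estimates with ~4 residual df are hugely noisy and often
  # non-positive; non-positive values are censored to the prior rather than
  # floored (a floored value would drag the blend toward zero), and the blend
  # is on the natural scale because a geometric blend is biased low, which
  # would make the downstream Wald test anticonservative
  informative <- !is.na(raw) & raw >= 1e-4
  prior <- if (any(informative)) mean(clip(raw[informative], lo, hi)) else lo
  tot_depth <- rowSums(N)
  w <- tot_depth / max(mean(tot_depth), 1)
  out <- ifelse(informative,
                (w * clip(raw, lo, hi) + prior) / (w + 1),
                prior)
  out <- clip(out, lo, hi)
  attr(out, "prior") <- prior
  out
}

#' Beta-binomial Wald test for a two-group methylation difference
#'
#' w = (mu1 - mu2) / sqrt(V1 + V2), where Vg is the beta-binomial variance of
#' the group's (smoothed) pooled mean estimator: Vg = mubar (1 - mubar)
#' ((1 - phi) sum(n) + phi sum(n^2)) / sum(n)^2, with mubar the pooled
#' two-group mean (floored away from 0/1). Two-sided p from the standard
#' normal. Sites with zero depth in either group are skipped (NA, flagged).
#'
#' @param m1,n1,m2,n2 methylated counts and depths per group: matrices (sites
#'   x samples) or vectors of already-pooled sums.
#' @param mu1,mu2 group mean methylation (e.g. smoothed); defaults to pooled
#'   raw means.
#' @param phi shrunk dispersion per site.
#' @param n1_sq,n2_sq optional sums of squared depths (used when `n1`, `n2`
#'   are already window-pooled sums; defaults to rowSums(n^2) for matrices or
#'   n^2 for vectors).
#' @return data.frame: mu1, mu2, phi, wald, p_value, tested.
#' @export
wald_site_test <- function(m1, n1, m2, n2, mu1 = NULL, mu2 = NULL, phi = 0,
                           n1_sq = NULL, n2_sq = NULL) {
  pool <- function(x) if (is.matrix(x)) rowSums(x) else x
  sq <- function(x) if (is.matrix(x)) rowSums(x^2) else x^2
  sm1 <- pool(m1); sn1 <- pool(n1); sm2 <- pool(m2); sn2 <- pool(n2)
  sn1_sq <- n1_sq %||% sq(n1)
  sn2_sq <- n2_sq %||% sq(n2)
  tested <- sn1 > 0 & sn2 > 0
  if (is.null(mu1)) mu1 <- ifelse(sn1 > 0, sm1 / sn1, NA_real_)
  if (is.null(mu2)) mu2 <- ifelse(sn2 > 0, sm2 / sn2, NA_real_)
  mubar <- ifelse(tested, (sm1 + sm2) / (sn1 + sn2), NA_real_)
  pq <- clip(mubar * (1 - mubar), 1e-3, 0.25)
  v1 <- pq * ((1 - phi) * sn1 + phi * sn1_sq) / sn1^2
  v2 <- pq * ((1 - phi) * sn2 + phi * sn2_sq) / sn2^2
  w <- ifelse(tested, (mu1 - mu2) / sqrt(v1 + v2), NA_real_)
  data.frame(mu1 = mu1, mu2 = mu2, phi = phi, wald = w,
             p_value = ifelse(tested, 2 * pnorm(-abs(w)), NA_real_),
             tested = tested)
}

#' Site-level differential methylation tests between two groups
#'
#' The full smoothed beta-binomial Wald chain: sites covered (depth >= 1) in
#' every sample of both groups are kept; within each (chromosome, context)
#' stream the group methylation means are smoothed by a coverage-weighted
#' moving average; per-site dispersions are estimated and shrunk genome-wide;
#' and each site is Wald-tested using the variance of the window-pooled mean
#' estimator. Contexts are tested in separate streams.
#'
#' @param reports named list of cytosine-report data.frames or paths.
#' @param samples data.frame with columns sample, group.
#' @param contrast character pair c(group_a, group_b); the test direction is
#'   group_a minus group_b.
#' @param window smoothing window in bp (default 500).
#' @param contexts contexts to test (default CG, CHG, CHH).
#' @param control_chrom excluded chromosome (default "lambda").
#' @param require_all_covered keep only sites with depth >= 1 in every sample
#'   (default TRUE).
#' @return data.frame of class `dmr_site_tests`: chrom, pos, strand, context,
#'   mu1, mu2, phi, wald, p_value plus raw pooled group counts (m1_raw,
#'   n1_raw, m2_raw, n2_raw); attribute `contrast`.
#' @export
dmr_site_tests <- function(reports, samples, contrast, window = 500L,
                           contexts = c("CG", "CHG", "CHH"),
                           control_chrom = "lambda",
                           require_all_covered = TRUE) {
  stopifnot(length(contrast) == 2L, all(contrast %in% samples$group))
  use <- samples$sample[samples$group %in% contrast]
  bs <- assemble_bs_counts(reports[use], control_chrom = control_chrom)
  grp <- samples$group[match(colnames(bs$M), samples$sample)]
  keep <- bs$sites$context %in% contexts
  if (require_all_covered) keep <- keep & rowSums(bs$N == 0) == 0
  sites <- bs$sites[keep, ]; M <- bs$M[keep, , drop = FALSE]
  N <- bs$N[keep, , drop = FALSE]
  if (nrow(sites) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      mu1 = numeric(0), mu2 = numeric(0), phi = numeric(0),
                      wald = numeric(0), p_value = numeric(0),
                      m1_raw = numeric(0), n1_raw = numeric(0),
                      m2_raw = numeric(0), n2_raw = numeric(0))
    attr(out, "contrast") <- contrast
    class(out) <- c("dmr_site_tests", "data.frame")
    return(out)
  }

  phi <- estimate_dispersion(M, N, grp)
  a_cols <- grp == contrast[1]; b_cols <- grp == contrast[2]
  m1 <- rowSums(M[, a_cols, drop = FALSE]); n1 <- rowSums(N[, a_cols, drop = FALSE])
  n1sq <- rowSums(N[, a_cols, drop = FALSE]^2)
  m2 <- rowSums(M[, b_cols, drop = FALSE]); n2 <- rowSums(N[, b_cols, drop = FALSE])
  n2sq <- rowSums(N[, b_cols, drop = FALSE]^2)

  # per-site group difference and its beta-binomial variance; the windowed
  # statistic is the inverse-variance weighted average of per-site
  # differences, so heterogeneous within-window methylation levels cancel
  # between groups instead of entering through group-specific depth weights
  p1 <- m1 / n1; p2 <- m2 / n2
  mu_t <- (m1 + m2 + 1) / (n1 + n2 + 2)
  pq <- clip(mu_t * (1 - mu_t), 1e-3, 0.25)
  vd <- pq * (((1 - phi) * n1 + phi * n1sq) / n1^2 +
                ((1 - phi) * n2 + phi * n2sq) / n2^2)
  cw <- 1 / vd

  stream <- paste(sites$chrom, sites$context)
  res <- vector("list", length(unique(stream)))
  names(res) <- unique(stream)
  for (st in unique(stream)) {
    i <- which(stream == st)
    i <- i[order(sites$pos[i])]
    half <- window / 2
    SM1 <- window_sum(sites$pos[i], m1[i], half)
    SN1 <- window_sum(sites$pos[i], n1[i], half)
    SM2 <- window_sum(sites$pos[i], m2[i], half)
    SN2 <- window_sum(sites$pos[i], n2[i], half)
    SC <- window_sum(sites$pos[i], cw[i], half)
    SCD <- window_sum(sites$pos[i], cw[i] * (p1[i] - p2[i]), half)
    w <- (SCD / SC) * sqrt(SC)
    res[[st]] <- cbind(sites[i, ],
                       data.frame(mu1 = SM1 / SN1, mu2 = SM2 / SN2,
                                  phi = phi[i], wald = w,
                                  p_value = 2 * pnorm(-abs(w))),
                       m1_raw = m1[i], n1_raw = n1[i], m2_raw = m2[i],
                       n2_raw = n2[i])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "window") <- window
  class(out) <- c("dmr_site_tests", "data.frame")
  out
}

#' Call differentially methylated regions from site tests
#'
#' Maximal runs of significant sites (p < `p_threshold`) with a consistent
#' difference sign, allowing gaps of at most `merge_gap` bp between
#' consecutive significant sites, become DMRs when the spanned region is at
#' least `min_len` bp long, contains at least `min_sites` tested sites, and at
#' least `pct_sig` of those member sites are significant. Runs never mix
#' contexts or chromosomes. Region methylation summaries use raw (unsmoothed)
#' pooled counts; coordinates are 1-based inclusive.
#'
#' @param site_tests a `dmr_site_tests` data.frame.
#' @param p_threshold site significance threshold (default 1e-5).
#' @param min_len minimum region length in bp (default 50).
#' @param min_sites minimum tested sites in the region (default 3).
#' @param pct_sig minimum fraction of member sites significant (default 0.5).
#' @param merge_gap maximum gap in bp between consecutive significant sites of
#'   one run (default 100).
#' @param refine_frac boundary refinement: candidate regions are trimmed from
#'   both ends while the local raw methylation difference (a +/-
#'   `refine_window`/2 bp coverage-weighted average of unsmoothed counts) is
#'   below this fraction of the run's peak difference or of the opposite
#'   sign. Smoothing lends power from neighbouring sites but blurs edges by up
#'   to half a window; at threshold 0.5 the trimmed boundary sits where the
#'   local difference crosses half its plateau, i.e. at the true edge of a
#'   step-shaped region. 0 disables (default 0.5).
#' @param refine_window width (bp) of the local averaging window used by the
#'   refinement (default 120).
#' @return data.frame of class `dmr_set`: chrom, start, end, length, n_sites,
#'   n_sig, mean_meth1, mean_meth2, meth_diff, areaStat, context, direction.
#' @export
call_dmrs <- function(site_tests, p_threshold = 1e-5, min_len = 50L,
                      min_sites = 3L, pct_sig = 0.5, merge_gap = 100L,
                      refine_frac = 0.5, refine_window = 120L) {
  contrast <- attr(site_tests, "contrast") %||% c("A", "B")
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      length = integer(0), n_sites = integer(0),
                      n_sig = integer(0), mean_meth1 = numeric(0),
                      mean_meth2 = numeric(0), meth_diff = numeric(0),
                      areaStat = numeric(0), context = character(0),
                      direction = character(0))
  rows <- list()
  d <- site_tests[!is.na(site_tests$p_value), ]
  for (st in unique(paste(d$chrom, d$context))) {
    s <- d[paste(d$chrom, d$context) == st, ]
    s <- s[order(s$pos), ]
    sig <- which(s$p_value < p_threshold)
    if (length(sig) == 0L) next
    local_diff <- if (refine_frac > 0) {
      rh <- refine_window / 2
      window_sum(s$pos, s$m1_raw, rh) / window_sum(s$pos, s$n1_raw, rh) -
        window_sum(s$pos, s$m2_raw, rh) / window_sum(s$pos, s$n2_raw, rh)
    } else rep(NA_real_, nrow(s))
    sgn <- sign(s$wald[sig])
    new_run <- c(TRUE, diff(s$pos[sig]) > merge_gap | diff(sgn) != 0)
    run_id <- cumsum(new_run)
    for (r in unique(run_id)) {
      member_sig <- sig[run_id == r]
      start <- s$pos[member_sig[1]]; end <- s$pos[member_sig[length(member_sig)]]
      inside <- which(s$pos >= start & s$pos <= end)
      if (refine_frac > 0 && length(inside) > 2L) {
        # the Wald profile is a plateau under smoothing, so the region's core
        # difference is anchored at the strongest local raw difference in the
        # run's direction, not at the argmax-z site
        sgn_run <- sign(s$wald[member_sig[1]])
        core <- max(sgn_run * local_diff[inside]) * sgn_run
        weak <- sign(local_diff[inside]) != sign(core) |
          abs(local_diff[inside]) < refine_frac * abs(core)
        keep_lo <- match(FALSE, weak)
        keep_hi <- length(weak) + 1L - match(FALSE, rev(weak))
        if (!is.na(keep_lo) && keep_hi - keep_lo + 1L >= 2L) {
          inside <- inside[keep_lo:keep_hi]
          start <- s$pos[inside[1]]; end <- s$pos[inside[length(inside)]]
          member_sig <- member_sig[member_sig %in% inside]
          if (length(member_sig) == 0L) next
        }
      }
      len <- end - start + 1L
      if (len < min_len || length(inside) < min_sites ||
          length(member_sig) / length(inside) < pct_sig) next
      mm1 <- sum(s$m1_raw[inside]) / sum(s$n1_raw[inside])
      mm2 <- sum(s$m2_raw[inside]) / sum(s$n2_raw[inside])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = s$chrom[1], start = start, end = end, length = len,
        n_sites = length(inside), n_sig = length(member_sig),
        mean_meth1 = mm1, mean_meth2 = mm2, meth_diff = mm1 - mm2,
        areaStat = sum(s$wald[inside]), context = s$context[1],
        direction = if (mm1 >= mm2) paste("higher at", contrast[1]) else
          paste("higher at", contrast[2]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "params") <- list(p_threshold = p_threshold, min_len = min_len,
                              min_sites = min_sites, pct_sig = pct_sig,
                              merge_gap = merge_gap)
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Methylation log2 fold change of a DMR
#'
#' log2((mean_meth1 + eps) / (mean_meth2 + eps)); the pseudo-fraction `eps`
#' guards against fully unmethylated regions.
#'
#' @param dmr a `dmr_set` row (or the whole data.frame, vectorised), or a
#'   numeric vector of group-1 means.
#' @param mean2 group-2 means when `dmr` is numeric.
#' @param eps pseudo-fraction (default 0.01).
#' @return log2 ratios.
#' @export
dmr_methylation_log2fc <- function(dmr, mean2 = NULL, eps = 0.01) {
  if (is.data.frame(dmr)) {
    m1 <- dmr$mean_meth1; m2 <- dmr$mean_meth2
  } else {
    m1 <- dmr; m2 <- mean2
  }
  log2((m1 + eps) / (m2 + eps))
}

#' Descriptive summaries of a DMR set
#'
#' @param dmrs a `dmr_set`.
#' @param catalog optional `feature_catalog` for feature intersections and
#'   per-gene DMR lists.
#' @param length_cutoff length cutoff for the reported fraction (default 200).
#' @return list: length_quantiles, frac_le_cutoff, mean_sites, per_chrom
#'   density, per_context counts, per_feature percentages (multi-label, may
#'   exceed 100 in total), genes (per-gene DMR counts split by direction).
#' @export
summarize_dmrs <- function(dmrs, catalog = NULL, length_cutoff = 200L) {
  out <- list(n = nrow(dmrs))
  if (nrow(dmrs) == 0L) return(out)
  out$length_quantiles <- quantile(dmrs$length, c(0, 0.25, 0.5, 0.75, 1))
  out$median_length <- median(dmrs$length)
  out$frac_le_cutoff <- mean(dmrs$length <= length_cutoff)
  out$mean_sites <- mean(dmrs$n_sites)
  out$per_context <- table(dmrs$context)
  out$per_chrom <- table(dmrs$chrom)
  if (!is.null(catalog)) {
    fa <- assign_features(dmrs, catalog)
    out$per_feature_pct <- 100 * table(fa$feature) / nrow(dmrs)
    assoc <- associate_gene(dmrs, catalog)
    if (nrow(assoc)) {
      assoc$direction <- dmrs$direction[assoc$query]
      out$genes <- as.data.frame(table(assoc$gene_id, assoc$direction))
      names(out$genes) <- c("gene_id", "direction", "n_dmrs")
      out$genes <- out$genes[out$genes$n_dmrs > 0, ]
    }
  }
  out
}

#' @export
print.dmr_set <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("DMR set (%s vs %s): %d regions\n", ct[1], ct[2], nrow(x)))
  if (nrow(x) > 0)
    cat(sprintf("  median length %d bp; mean %.1f sites; contexts: %s\n",
                as.integer(median(x$length)), mean(x$n_sites),
                paste(names(table(x$context)), table(x$context),
                      sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
print.dmr_site_tests <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Site-level methylation tests (%s vs %s): %d sites\n",
              ct[1], ct[2], nrow(x)))
  invisible(x)
}
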