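test_that("smoothing is a coverage-weighted moving average with fixed points", {
  # hand case: three sites in one window, coverages 10/10/20, fractions 0/1/0.5
  sm <- smooth_methylation(pos = c(100L, 200L, 300L), m = c(0L, 10L, 10L),
                           n = c(10L, 10L, 20L), window = 500L)
  expect_equal(sm$smoothed[2], (0 * 10 + 1 * 10 + 0.5 * 20) / 40)
  # constant fractions are unchanged everywhere
  smc <- smooth_methylation(pos = c(1L, 50L, 99L), m = c(3L, 6L, 12L),
                            n = c(10L, 20L, 40L), window = 500L)
  expect_equal(smc$smoothed, rep(0.3, 3))
  # an isolated site is returned unchanged
  iso <- smooth_methylation(pos = c(100L, 10000L), m = c(7L, 1L),
                            n = c(10L, 10L), window = 500L)
  expect_equal(iso$smoothed, c(0.7, 0.1))
})

test_that("dispersion shrinkage degenerates and recovers as designed", {
  # identical replicate proportions (phi -> 0): deep sites end near the floor
  N <- matrix(200L, 50, 6); M <- matrix(100L, 50, 6)
  phi <- estimate_dispersion(M, N, rep(c("A", "B"), each = 3))
  expect_lt(mean(phi), 1e-3)
  # a single site with no replicate information takes the prior exactly
  phi1 <- estimate_dispersion(matrix(c(3L, 5L), 1, 2),
                              matrix(c(10L, 10L), 1, 2), c("A", "B"))
  expect_equal(unname(phi1[1]), attr(phi1, "prior"))
  # parameter recovery: phi = 0.1, depth 30, 1000 sites
  set.seed(7)
  k <- 6
  N <- matrix(30L, 1000, k)
  p <- matrix(rbeta(1000 * k, 0.3 * 9, 0.7 * 9), 1000, k)
  M <- matrix(rbinom(1000 * k, 30, p), 1000, k)
  phi2 <- estimate_dispersion(M, N, rep(c("A", "B"), each = 3))
  expect_gt(mean(phi2), 0.05)
  expect_lt(mean(phi2), 0.2)
})

test_that("the Wald site test is symmetric, null-calibrated, and skips zero depth", {
  # equal means: w = 0, p = 1
  wt <- wald_site_test(m1 = 5, n1 = 10, m2 = 10, n2 = 20, phi = 0.01)
  expect_equal(wt$wald, 0)
  expect_equal(wt$p_value, 1)
  # swapping groups negates w, p unchanged; w sign follows mu1 - mu2
  a <- wald_site_test(m1 = 8, n1 = 10, m2 = 3, n2 = 10, phi = 0.05)
  b <- wald_site_test(m1 = 3, n1 = 10, m2 = 8, n2 = 10, phi = 0.05)
  expect_equal(a$wald, -b$wald)
  expect_equal(a$p_value, b$p_value)
  expect_equal(sign(a$wald), sign(a$mu1 - a$mu2))
  # zero depth in one group: skipped, recorded
  z <- wald_site_test(m1 = 0, n1 = 0, m2 = 5, n2 = 10, phi = 0.01)
  expect_false(z$tested)
  expect_true(is.na(z$p_value))
  # type-I Monte Carlo: mu = 0.3 both groups, phi = 0.05, 2000 sites
  set.seed(8)
  k <- 6
  p <- matrix(rbeta(2000 * k, 0.3 * 19, 0.7 * 19), 2000, k)
  N <- matrix(30L, 2000, k)
  M <- matrix(rbinom(2000 * k, 30, p), 2000, k)
  phi <- estimate_dispersion(M, N, rep(c("A", "B"), each = 3))
  wt <- wald_site_test(M[, 1:3], N[, 1:3], M[, 4:6], N[, 4:6], phi = phi)
  fr <- mean(wt$p_value < 0.05, na.rm = TRUE)
  expect_gt(fr, 0.02)
  expect_lt(fr, 0.10)
})

test_that("DMR merging and thresholds behave as specified on crafted input", {
  mk_sites <- function(pos, p, wald) {
    out <- data.frame(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                      mu1 = 0.8, mu2 = 0.5, phi = 0.01, wald = wald,
                      p_value = p, m1_raw = 24, n1_raw = 30, m2_raw = 15,
                      n2_raw = 30)
    attr(out, "contrast") <- c("A", "B")
    class(out) <- c("dmr_site_tests", "data.frame")
    out
  }
  # no significant site: empty set
  empty <- call_dmrs(mk_sites(seq(1, 2000, 50), 0.5, 1))
  expect_equal(nrow(empty), 0)

  # two significant runs 150 bp apart: separate at merge_gap 100, one at 200
  pos <- c(seq(1000, 1090, 30), seq(1240, 1330, 30))
  st <- mk_sites(pos, 1e-8, 8)
  two <- call_dmrs(st, merge_gap = 100L, refine_frac = 0)
  expect_equal(nrow(two), 2)
  one <- call_dmrs(st, merge_gap = 200L, refine_frac = 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 1000)
  expect_equal(one$end, 1330)
  expect_equal(one$meth_diff, 24 / 30 - 15 / 30, tolerance = 1e-12)
  expect_match(one$direction, "higher at A")

  # opposite-sign adjacent runs never merge
  st2 <- mk_sites(pos, 1e-8, c(rep(8, 4), rep(-8, 4)))
  st2$mu1[5:8] <- 0.2; st2$m1_raw[5:8] <- 6
  expect_equal(nrow(call_dmrs(st2, merge_gap = 500L, refine_frac = 0)), 2)

  # min_len and min_sites gate the calls
  expect_equal(nrow(call_dmrs(mk_sites(c(1000, 1010), 1e-8, 8),
                              min_sites = 3L, refine_frac = 0)), 0)
  expect_equal(nrow(call_dmrs(mk_sites(c(1000, 1010, 1020), 1e-8, 8),
                              min_len = 50L, refine_frac = 0)), 0)
})

test_that("relaxing the site threshold never shrinks the called DMR set", {
  msim <- small_methylome()
  st <- dmr_site_tests(msim$reports, msim$samples, c("4M", "6M"), contexts = "CG")
  strict <- call_dmrs(st, p_threshold = 1e-6)
  loose <- call_dmrs(st, p_threshold = 1e-4)
  # every strict DMR is covered by a loose DMR
  for (i in seq_len(nrow(strict))) {
    covered <- any(loose$chrom == strict$chrom[i] &
                     loose$start <= strict$start[i] + strict$length[i] / 2 &
                     loose$end >= strict$end[i] - strict$length[i] / 2)
    expect_true(covered, label = sprintf("strict DMR %d covered", i))
  }
  expect_gte(nrow(loose), nrow(strict))
})

test_that("planted DMRs are recovered in place and context streams never mix", {
  msim <- small_methylome()
  st <- dmr_site_tests(msim$reports, msim$samples, c("4M", "6M"))
  expect_true(all(st$context %in% c("CG", "CHG", "CHH")))
  dmrs <- call_dmrs(st)
  expect_true(all(dmrs$context %in% c("CG", "CHG", "CHH")))
  tr <- msim$truth
  for (i in seq_len(nrow(tr))) {
    hit <- any(dmrs$chrom == tr$chrom[i] & dmrs$start <= tr$end[i] &
                 dmrs$end >= tr$start[i] &
                 sign(dmrs$meth_diff) == sign(tr$delta[i]))
    expect_true(hit, label = sprintf("planted DMR %d recovered", i))
  }
  # direction labels agree with planted deltas via the gene map
  smry <- summarize_dmrs(dmrs, small_catalog())
  expect_equal(smry$n, nrow(dmrs))
  expect_true(all(dmrs$length == dmrs$end - dmrs$start + 1))
})

test_that("a planted 200 bp region is recovered with tight boundaries", {
  good <- 0; n_seeds <- 6
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(seed = seed, n_chroms = 1L, chrom_length = 60000L,
                      n_genes = 4L, n_dmrs = 1L, dmr_len_range = c(200L, 200L),
                      cpg_rate = 150, dmr_pairs = list(c("4M", "6M")),
                      dmr_share_frac = 0, control_chrom_length = 1000L)
    msim <- simulate_methylome(cfg, build_toy_annotation(cfg))
    st <- dmr_site_tests(msim$reports, msim$samples, c("4M", "6M"),
                         contexts = "CG")
    dmrs <- call_dmrs(st)
    tr <- msim$truth
    for (j in seq_len(nrow(dmrs))) {
      inter <- min(tr$end, dmrs$end[j]) - max(tr$start, dmrs$start[j]) + 1
      uni <- max(tr$end, dmrs$end[j]) - min(tr$start, dmrs$start[j]) + 1
      if (inter > 0 && inter / uni >= 0.8) good <- good + 1
    }
  }
  expect_gte(good, round(0.9 * n_seeds) - 1)
})

test_that("DMR methylation log2FC is exact and antisymmetric", {
  expect_equal(dmr_methylation_log2fc(0.5, 0.5), 0)
  expect_equal(dmr_methylation_log2fc(0.8, 0.19), log2(0.81 / 0.20))
  expect_equal(round(dmr_methylation_log2fc(0.8, 0.19), 3), 2.018)
  expect_equal(dmr_methylation_log2fc(0.19, 0.8),
               -dmr_methylation_log2fc(0.8, 0.19))
  # data.frame interface
  d <- data.frame(mean_meth1 = 0.8, mean_meth2 = 0.19)
  expect_equal(dmr_methylation_log2fc(d), log2(0.81 / 0.20))
})

test_that("DMR summaries report lengths, contexts and per-gene direction", {
  one <- data.frame(chrom = "chr1", start = 1000L, end = 1106L, length = 107L,
                    n_sites = 10L, n_sig = 9L, mean_meth1 = 0.8,
                    mean_meth2 = 0.5, meth_diff = 0.3, areaStat = 50,
                    context = "CG", direction = "higher at A")
  class(one) <- c("dmr_set", "data.frame")
  sm <- summarize_dmrs(one, length_cutoff = 200L)
  expect_equal(sm$median_length, 107)
  expect_equal(sm$frac_le_cutoff, 1.0)
  expect_equal(sm$mean_sites, 10)
  # multi-label feature counts can exceed the DMR count
  msim <- small_methylome()
  st <- dmr_site_tests(msim$reports, msim$samples, c("4M", "6M"), contexts = "CG")
  dmrs <- call_dmrs(st)
  if (nrow(dmrs) > 0) {
    sm2 <- summarize_dmrs(dmrs, small_catalog())
    expect_gte(sum(sm2$per_feature_pct) / 100 * nrow(dmrs), 0)
  }
})
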