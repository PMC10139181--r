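test_that("toy annotation is deterministic, capacity-checked and structurally sound", {
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_toy_annotation(cfg, out_dir = d1)
  build_toy_annotation(cfg, out_dir = d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)

  cat <- small_catalog()
  # genes must not overlap one another
  ov <- GenomicRanges::findOverlaps(cat$genes, ignore.strand = TRUE,
                                    drop.self = TRUE)
  expect_length(ov, 0)
  # introns == gene span minus exons, per gene (set identity over positions)
  for (i in seq_along(cat$genes)) {
    gid <- cat$genes$gene_id[i]
    span <- seq(GenomicRanges::start(cat$genes[i]), GenomicRanges::end(cat$genes[i]))
    ex <- cat$exons[cat$exons$gene_id == gid]
    expos <- unlist(Map(seq, GenomicRanges::start(ex), GenomicRanges::end(ex)))
    intr <- cat$introns[cat$introns$gene_id == gid]
    inpos <- if (length(intr)) unlist(Map(seq, GenomicRanges::start(intr),
                                          GenomicRanges::end(intr))) else integer(0)
    expect_setequal(inpos, setdiff(span, expos))
  }
  # shores never overlap CGIs; everything within chromosome bounds
  expect_length(GenomicRanges::findOverlaps(cat$shores, cat$cgi), 0)
  for (slot in c("genes", "exons", "cgi", "shores", "repeats"))
    expect_true(all(GenomicRanges::end(cat[[slot]]) <= cat$chrom_sizes[
      as.character(GenomicRanges::seqnames(cat[[slot]]))]), label = slot)

  # empty genome still carries chromosome sizes
  empty <- build_toy_annotation(small_config(n_genes = 0L, n_dmrs = 0L))
  expect_length(empty$genes, 0)
  expect_identical(empty$chrom_sizes, cat$chrom_sizes)

  # a genome too small for the requested genes errors out explicitly
  expect_error(build_toy_annotation(sim_config(n_chroms = 1L, chrom_length = 5000L,
                                               n_genes = 50L)),
               "capacity")
})

test_that("simulated methylome conserves counts, plants effects, and round-trips", {
  msim <- small_methylome()
  cfg <- small_config()
  r <- msim$reports[[1]]
  expect_true(all(r$count_methylated >= 0 & r$count_unmethylated >= 0))

  # determinism: same seed, bit-identical files
  d1 <- withr::local_tempdir()
  simulate_methylome(cfg, small_catalog(), out_dir = d1)
  f <- file.path(d1, paste0(names(msim$reports)[1], ".CX_report.txt"))
  reread <- read_cytosine_report(f)
  expect_equal(nrow(reread), nrow(r))  # lossless round-trip
  expect_equal(reread$count_methylated, r$count_methylated)
  msim2 <- simulate_methylome(cfg, small_catalog())
  expect_identical(msim$reports, msim2$reports)

  # planted DMRs live inside chromosomes and recover their delta on average
  tr <- msim$truth
  expect_true(all(tr$start >= 1 & tr$end <= cfg$chrom_length))
  for (i in seq_len(nrow(tr))) {
    ga <- msim$samples$sample[msim$samples$group == tr$group_a[i]]
    gb <- msim$samples$sample[msim$samples$group == tr$group_b[i]]
    inside <- function(rep) rep$chrom == tr$chrom[i] & rep$pos >= tr$start[i] &
      rep$pos <= tr$end[i] & rep$context == "CG"
    frac <- function(ss) {
      m <- 0; n <- 0
      for (s in ss) {
        rep <- msim$reports[[s]]; sel <- inside(rep)
        m <- m + sum(rep$count_methylated[sel])
        n <- n + sum(rep$count_methylated[sel] + rep$count_unmethylated[sel])
      }
      c(m = m, n = n)
    }
    fa <- frac(ga); fb <- frac(gb)
    diff_obs <- fa["m"] / fa["n"] - fb["m"] / fb["n"]
    se <- sqrt(0.25 / fa["n"] + 0.25 / fb["n"]) +
      sqrt(2 * cfg$site_dispersion / tr$n_sites[i])
    expect_lt(abs(diff_obs - tr$delta[i]), 3 * se + 0.05)
  }
})

test_that("a null methylome configuration shows no group differences", {
  cfg <- small_config(seed = 202L, n_dmrs = 0L, conversion_failure = 0)
  msim <- simulate_methylome(cfg, build_toy_annotation(cfg))
  pool <- function(g) {
    m <- 0; n <- 0
    for (s in msim$samples$sample[msim$samples$group == g]) {
      r <- msim$reports[[s]]
      sel <- r$chrom != "lambda"
      m <- m + sum(r$count_methylated[sel])
      n <- n + sum(r$count_methylated[sel] + r$count_unmethylated[sel])
    }
    c(m, n)
  }
  a <- pool("4M"); b <- pool("6M")
  diff <- a[1] / a[2] - b[1] / b[2]
  se <- sqrt(0.25 / a[2] + 0.25 / b[2]) + sqrt(2 * cfg$site_dispersion / 16000)
  expect_lt(abs(diff), 3 * se)
})

test_that("simulated expression matches its generative model", {
  esim <- small_expression()
  cfg <- small_config()
  expect_identical(dim(esim$counts), c(length(small_catalog()$genes),
                                       cfg$n_groups * cfg$n_per_group))
  expect_true(all(esim$counts == round(esim$counts) & esim$counts >= 0))
  # deterministic
  esim2 <- simulate_expression(cfg, small_catalog())
  expect_identical(esim$counts, esim2$counts)
  # planted fold changes reproduce in group means of size-factor-corrected counts
  y <- sweep(esim$counts, 2, esim$size_factors, "/")
  for (i in seq_len(nrow(esim$truth))) {
    tr <- esim$truth[i, ]
    ra <- mean(y[tr$gene_id, esim$samples$group == tr$group_a])
    rb <- mean(y[tr$gene_id, esim$samples$group == tr$group_b])
    expect_lt(abs(log2(ra / rb) - tr$true_log2fc), log2(1.6))
  }
  # empty truth and error cases
  e0 <- simulate_expression(small_config(n_degs = 0L), small_catalog())
  expect_equal(nrow(e0$truth), 0)
  expect_error(simulate_expression(small_config(n_degs = 1000L), small_catalog()),
               "n_degs")
})

test_that("sim_config validates fractions, ranges and counts", {
  expect_error(sim_config(frac_chh_chg = 1.5), "fractions")
  expect_error(sim_config(dmr_len_range = c(100L, 50L)), "dmr_len_range")
  expect_error(sim_config(dmr_delta = 2), "dmr_delta")
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(group_names = c("A", "B")), "group_names")
})
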