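test_that("hand-built GTF loads with exact strand-aware promoters and introns", {
  dir <- write_two_gene_annotation(withr::local_tempdir())
  cat <- load_annotation(file.path(dir, "genes.gtf"), file.path(dir, "cgi.bed"),
                         file.path(dir, "repeats.bed"),
                         file.path(dir, "chrom.sizes"))
  expect_length(cat$genes, 2)
  # plus-strand gene gA: TSS 5000, promoter 4000..5000
  pa <- cat$promoters[cat$promoters$gene_id == "gA"]
  expect_equal(GenomicRanges::start(pa), 4000)
  expect_equal(GenomicRanges::end(pa), 5000)
  # minus-strand gene gB: TSS 24000, promoter 24000..25000 (reflected side)
  pb <- cat$promoters[cat$promoters$gene_id == "gB"]
  expect_equal(GenomicRanges::start(pb), 24000)
  expect_equal(GenomicRanges::end(pb), 25000)
  # introns are the exon gaps
  ia <- cat$introns[cat$introns$gene_id == "gA"]
  expect_equal(GenomicRanges::start(ia), 5401)
  expect_equal(GenomicRanges::end(ia), 7599)
  # a single-exon gene has no introns
  writeLines(c('chr1\ttest\tgene\t100\t500\t.\t+\t.\tgene_id "g1";',
               'chr1\ttest\texon\t100\t500\t.\t+\t.\tgene_id "g1";'),
             file.path(dir, "one.gtf"))
  cat1 <- load_annotation(file.path(dir, "one.gtf"), file.path(dir, "cgi.bed"),
                          file.path(dir, "repeats.bed"),
                          file.path(dir, "chrom.sizes"))
  expect_length(cat1$introns, 0)
  # toy-genome GTF round-trips with identical gene count
  d2 <- withr::local_tempdir()
  write_catalog(small_catalog(), d2)
  cat2 <- load_annotation(file.path(d2, "genes.gtf"), file.path(d2, "cgi.bed"),
                          file.path(d2, "repeats.bed"),
                          file.path(d2, "chrom.sizes"))
  expect_equal(length(cat2$genes), length(small_catalog()$genes))
  expect_equal(sort(cat2$genes$gene_id), sort(small_catalog()$genes$gene_id))
})

test_that("gene association honours the 1 kb rule exactly at the boundary", {
  dir <- write_two_gene_annotation(withr::local_tempdir())
  cat <- load_annotation(file.path(dir, "genes.gtf"), file.path(dir, "cgi.bed"),
                         file.path(dir, "repeats.bed"),
                         file.path(dir, "chrom.sizes"))
  # gA spans 5000..8000 (+): a point 999 bp upstream of the TSS associates,
  # 1001 bp does not
  q999 <- data.frame(chrom = "chr1", start = 5000 - 999, end = 5000 - 999)
  q1001 <- data.frame(chrom = "chr1", start = 5000 - 1001, end = 5000 - 1001)
  expect_true("gA" %in% associate_gene(q999, cat)$gene_id)
  expect_false("gA" %in% associate_gene(q1001, cat)$gene_id)
  # and exactly 1000 bp downstream of the TTS still associates
  q1000 <- data.frame(chrom = "chr1", start = 8000 + 1000, end = 8000 + 1000)
  expect_true("gA" %in% associate_gene(q1000, cat)$gene_id)
})

test_that("feature assignment and gene association match a quadratic oracle", {
  cat <- small_catalog()
  set.seed(33)
  n_q <- 120
  qs <- sample.int(small_config()$chrom_length - 600L, n_q)
  queries <- data.frame(chrom = "chr1", start = qs,
                        end = qs + sample(1:600, n_q, replace = TRUE))
  fa <- assign_features(queries, cat)
  slots <- c(cgi = "cgi", shore = "shores", promoter = "promoters",
             utr5 = "utr5", utr3 = "utr3", exon = "exons", intron = "introns",
             `repeat` = "repeats")
  for (lbl in names(slots)) {
    gr <- cat[[slots[[lbl]]]]
    hits <- brute_overlaps(queries$start, queries$end, queries$chrom,
                           GenomicRanges::start(gr), GenomicRanges::end(gr),
                           as.character(GenomicRanges::seqnames(gr)))
    expect_setequal(fa$query[fa$feature == lbl], unique(hits[, 1]))
  }
  # gene association vs brute force on flank-extended spans
  flank <- 1000L
  assoc <- associate_gene(queries, cat, flank = flank)
  g <- cat$genes
  hits <- brute_overlaps(queries$start, queries$end, queries$chrom,
                         pmax(1L, GenomicRanges::start(g) - flank),
                         GenomicRanges::end(g) + flank,
                         as.character(GenomicRanges::seqnames(g)))
  expect_setequal(paste(assoc$query, assoc$gene_id),
                  paste(hits[, 1], g$gene_id[hits[, 2]]))
  # multi-label: an interval spanning an exon-intron junction carries both
  gid <- cat$genes$gene_id[1]
  ex1 <- cat$exons[cat$exons$gene_id == gid][1]
  junction <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex1)),
                         start = GenomicRanges::end(ex1) - 5,
                         end = GenomicRanges::end(ex1) + 5)
  labs <- assign_features(junction, cat)$feature
  expect_true(all(c("exon", "intron") %in% labs))
  # intergenic interval far from everything is unlabeled
  far <- data.frame(chrom = "chrZ", start = 1, end = 10)
  expect_equal(nrow(suppressWarnings(assign_features(far, cat))), 0)
})

test_that("reversing a gene's strand reflects its promoter across the TSS", {
  cat <- small_catalog()
  g <- cat$genes[1]
  flipped <- g
  GenomicRanges::strand(flipped) <- if (as.character(GenomicRanges::strand(g)) == "+")
    "-" else "+"
  p1 <- methdyn:::derive_promoters(g, cat$chrom_sizes)
  p2 <- methdyn:::derive_promoters(flipped, cat$chrom_sizes)
  expect_false(identical(GenomicRanges::start(p1), GenomicRanges::start(p2)))
  tss1 <- if (as.character(GenomicRanges::strand(g)) == "+")
    GenomicRanges::start(g) else GenomicRanges::end(g)
  expect_true(tss1 >= GenomicRanges::start(p1) && tss1 <= GenomicRanges::end(p1))
})

test_that("feature methylation profile averages fractions, never fabricates zeros", {
  cat <- small_catalog()
  pr <- cat$promoters[1]
  pos <- GenomicRanges::start(pr) + c(10L, 20L)
  calls <- call_true_methylated(data.frame(
    chrom = as.character(GenomicRanges::seqnames(pr)), pos = pos, strand = "+",
    count_methylated = c(0L, 10L), count_unmethylated = c(10L, 0L),
    context = "CG", trinucleotide = "CGA"))
  prof <- feature_methylation_profile(list(s1 = calls), cat)
  expect_equal(prof$meth_pct[prof$feature == "promoter"], 50)
  # features containing no tested site are NA, not zero
  expect_true(is.na(prof$meth_pct[prof$feature == "repeat"]))

  # planted per-feature means recover their ordering
  cfg <- small_config(seed = 77L,
                      baseline_meth_by_feature = list(promoter = 0.1, intron = 0.6))
  msim <- simulate_methylome(cfg, small_catalog())
  calls_all <- lapply(msim$reports, call_true_methylated)
  prof2 <- feature_methylation_profile(calls_all, small_catalog())
  m <- tapply(prof2$meth_pct, prof2$feature, mean, na.rm = TRUE)
  expect_lt(m[["promoter"]], m[["intron"]])
})

test_that("group statistics match hand computations", {
  # Dunn z for {1,2,3} vs {4,5,6}: mean ranks 2 and 5, no ties
  dz <- dunn_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(dz$z, 3 / sqrt((6 * 7 / 12) * (2 / 3)), tolerance = 1e-10)
  expect_equal(round(dz$z, 3), 1.964)

  # identical feature distributions: ANOVA F ~ 0, p ~ 1
  prof <- expand.grid(feature = c("exon", "intron", "promoter"),
                      sample = paste0("s", 1:6), stringsAsFactors = FALSE)
  prof$meth_pct <- rep(c(10, 20, 30, 10, 20, 30), each = 3)
  groups <- setNames(rep(c("4M", "6M"), each = 3), paste0("s", 1:6))
  gs <- suppressWarnings(group_stats(prof, groups))
  expect_lt(gs$anova$F, 1e-10)
  expect_gt(gs$anova$p_value, 0.999)
  expect_equal(nrow(gs$shapiro), 3)

  # groups with <3 observations skip normality with a warning
  prof_small <- prof[prof$sample %in% c("s1", "s2"), ]
  w <- capture_warnings(group_stats(prof_small, groups))
  expect_true(any(grepl("skipped", w)))
})

test_that("a planted stage shift is flagged significant in most seeded runs", {
  hits <- 0; n_runs <- 10
  for (seed in seq_len(n_runs)) {
    set.seed(seed)
    # promoter methylation higher at 10M, as a stage-shifted profile table
    prof <- expand.grid(feature = c("promoter", "intron"),
                        sample = paste0("s", 1:9), stringsAsFactors = FALSE)
    groups <- setNames(rep(c("4M", "6M", "10M"), each = 3), paste0("s", 1:9))
    base <- ifelse(prof$feature == "promoter", 20, 60)
    shift <- ifelse(groups[prof$sample] == "10M" & prof$feature == "promoter", 8, 0)
    prof$meth_pct <- base + shift + rnorm(nrow(prof), 0, 2)
    gs <- suppressWarnings(group_stats(prof, groups))
    dn <- gs$dunn[gs$dunn$feature == "promoter" &
                    (gs$dunn$group_a == "10M" | gs$dunn$group_b == "10M"), ]
    if (any(dn$p_value < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
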