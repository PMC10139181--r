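# shared fixtures, built once per test session
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

small_config <- function(...) {
  defaults <- list(seed = 101L, n_chroms = 1L, chrom_length = 80000L,
                   n_genes = 6L, n_degs = 4L, n_dmrs = 2L,
                   dmr_len_range = c(150L, 400L),
                   dmr_pairs = list(c("4M", "6M")), dmr_share_frac = 0,
                   control_chrom_length = 20000L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_catalog <- function() memo("small_catalog", build_toy_annotation(small_config()))

small_methylome <- function() memo("small_methylome",
                                   simulate_methylome(small_config(), small_catalog()))

small_expression <- function() memo("small_expression",
                                    simulate_expression(small_config(), small_catalog()))

# independent quadratic interval-overlap oracle (1-based inclusive)
brute_overlaps <- function(qs, qe, qchrom, fs, fe, fchrom) {
  hits <- list()
  for (i in seq_along(qs)) for (j in seq_along(fs))
    if (qchrom[i] == fchrom[j] && qs[i] <= fe[j] && fs[j] <= qe[i])
      hits[[length(hits) + 1L]] <- c(i, j)
  if (length(hits) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# a hand-rolled two-gene annotation on disk (GTF + BEDs + chrom.sizes)
write_two_gene_annotation <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- c(
    'chr1\ttest\tgene\t5000\t8000\t.\t+\t.\tgene_id "gA"; gene_name "ALPHA";',
    'chr1\ttest\texon\t5000\t5400\t.\t+\t.\tgene_id "gA"; gene_name "ALPHA";',
    'chr1\ttest\texon\t7600\t8000\t.\t+\t.\tgene_id "gA"; gene_name "ALPHA";',
    'chr1\ttest\tfive_prime_utr\t5000\t5100\t.\t+\t.\tgene_id "gA"; gene_name "ALPHA";',
    'chr1\ttest\tthree_prime_utr\t7900\t8000\t.\t+\t.\tgene_id "gA"; gene_name "ALPHA";',
    'chr1\ttest\tgene\t20000\t24000\t.\t-\t.\tgene_id "gB"; gene_name "BETA";',
    'chr1\ttest\texon\t20000\t21000\t.\t-\t.\tgene_id "gB"; gene_name "BETA";',
    'chr1\ttest\texon\t23000\t24000\t.\t-\t.\tgene_id "gB"; gene_name "BETA";',
    'chr1\ttest\tfive_prime_utr\t23900\t24000\t.\t-\t.\tgene_id "gB"; gene_name "BETA";',
    'chr1\ttest\tthree_prime_utr\t20000\t20100\t.\t-\t.\tgene_id "gB"; gene_name "BETA";')
  writeLines(gtf, file.path(dir, "genes.gtf"))
  writeLines("chr1\t4500\t5200\tcgi1\t0\t.", file.path(dir, "cgi.bed"))
  writeLines("chr1\t30000\t30400\trep1\t0\t.", file.path(dir, "repeats.bed"))
  writeLines("chr1\t50000", file.path(dir, "chrom.sizes"))
  dir
}
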