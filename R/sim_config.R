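#' Simulation configuration
#'
#' Builds the configuration object consumed by [build_toy_annotation()],
#' [simulate_methylome()] and [simulate_expression()]. Defaults emulate the
#' design of a three-stage gestational study (three groups of three biological
#' replicates) profiled by RRBS: planted differentially methylated regions of
#' 50-500 bp with ~30% methylation differences, an unmethylated lambda
#' spike-in chromosome with a 0.59% conversion-failure rate (i.e. a 99.41%
#' bisulfite conversion rate), ~2% of cytosines in non-CG context, and
#' negative-binomial expression counts with planted |log2FC| = 1.5 effects.
#'
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @param n_groups,group_names number and labels of sample groups.
#' @param n_per_group biological replicates per group.
#' @param n_chroms,chrom_length genomic chromosomes and their common length (bp).
#' @param n_genes genes placed on the toy genome.
#' @param cpg_rate expected CpG dinucleotides per kb. The default (100/kb) is
#'   CGI-like, reflecting the CpG-dense MspI fragments RRBS enriches for.
#' @param coverage_mean,coverage_dispersion per-site read depth is drawn from a
#'   negative binomial with this mean and size (larger size = tighter depth).
#' @param baseline_meth_by_feature named list/vector of per-feature mean
#'   methylation fractions; entries override the built-in defaults. Recognised
#'   names: cgi, shore, promoter, utr5, utr3, exon, intron, repeat, intergenic,
#'   non_cg.
#' @param site_dispersion beta-binomial dispersion phi in (0,1); the
#'   across-replicate variance of a site with depth n and mean mu is
#'   n*mu*(1-mu)*(1+(n-1)*phi); phi = 0 degenerates to binomial.
#' @param n_dmrs number of planted DMRs.
#' @param dmr_delta methylation difference planted inside DMRs.
#' @param dmr_len_range length range (bp) of planted DMRs.
#' @param dmr_pairs list of group pairs to cycle DMRs over; default all
#'   pairwise combinations of the groups.
#' @param dmr_share_frac fraction of planted DMRs shared by two group pairs
#'   (emulating genes recurrently differentially methylated across
#'   comparisons).
#' @param frac_chh_chg fraction of simulated cytosines in CHG/CHH context.
#' @param conversion_failure probability that a truly unmethylated cytosine is
#'   read as methylated (bisulfite conversion failure).
#' @param control_chrom,control_chrom_length,control_site_rate name, length and
#'   per-strand cytosine density of the unmethylated spike-in control
#'   chromosome.
#' @param n_degs,deg_log2fc planted differentially expressed genes and their
#'   absolute log2 fold change.
#' @param nb_dispersion,mean_expr negative-binomial dispersion (alpha) and mean
#'   of simulated expression counts.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_groups = 3L,
                       group_names = c("4M", "6M", "10M"),
                       n_per_group = 3L,
                       n_chroms = 2L,
                       chrom_length = 300000L,
                       n_genes = 30L,
                       cpg_rate = 100,
                       coverage_mean = 30,
                       coverage_dispersion = 8,
                       baseline_meth_by_feature = list(),
                       site_dispersion = 0.02,
                       n_dmrs = 9L,
                       dmr_delta = 0.30,
                       dmr_len_range = c(50L, 500L),
                       dmr_pairs = NULL,
                       dmr_share_frac = 0.15,
                       frac_chh_chg = 0.02,
                       conversion_failure = 0.0059,
                       control_chrom = "lambda",
                       control_chrom_length = 200000L,
                       control_site_rate = 0.25,
                       n_degs = 10L,
                       deg_log2fc = 1.5,
                       nb_dispersion = 0.1,
                       mean_expr = 200) {
  # bimodal CpG methylation, as in mammalian genomes: CGIs/promoters/5' UTRs
  # hypomethylated, gene bodies / repeats / background heavily methylated
  base_meth <- list(cgi = 0.20, shore = 0.45, promoter = 0.15, utr5 = 0.10,
                    utr3 = 0.85, exon = 0.85, intron = 0.80, `repeat` = 0.90,
                    intergenic = 0.80, non_cg = 0.02)
  stopifnot(is.list(baseline_meth_by_feature) || is.numeric(baseline_meth_by_feature))
  for (nm in names(baseline_meth_by_feature))
    base_meth[[nm]] <- baseline_meth_by_feature[[nm]]
  if (length(group_names) != n_groups)
    stop("group_names must have length n_groups")
  if (is.null(dmr_pairs)) {
    cb <- combn(group_names, 2L)
    dmr_pairs <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  fracs <- c(unlist(base_meth), frac_chh_chg = frac_chh_chg,
             conversion_failure = conversion_failure,
             site_dispersion = site_dispersion,
             dmr_share_frac = dmr_share_frac)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must lie in [0, 1]")
  if (abs(dmr_delta) > 1) stop("dmr_delta must lie in [-1, 1]")
  if (length(dmr_len_range) != 2L || dmr_len_range[1] < 1 ||
      dmr_len_range[2] < dmr_len_range[1])
    stop("dmr_len_range must be an increasing pair with min >= 1")
  for (nm in c("n_groups", "n_per_group", "n_chroms", "chrom_length",
               "n_genes", "n_dmrs", "n_degs"))
    stop_if_not_scalar_count(get(nm), nm)
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              group_names = group_names, n_per_group = as.integer(n_per_group),
              n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), cpg_rate = cpg_rate,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              baseline_meth_by_feature = base_meth,
              site_dispersion = site_dispersion, n_dmrs = as.integer(n_dmrs),
              dmr_delta = dmr_delta, dmr_len_range = as.integer(dmr_len_range),
              dmr_pairs = dmr_pairs, dmr_share_frac = dmr_share_frac,
              frac_chh_chg = frac_chh_chg,
              conversion_failure = conversion_failure,
              control_chrom = control_chrom,
              control_chrom_length = as.integer(control_chrom_length),
              control_site_rate = control_site_rate,
              n_degs = as.integer(n_degs), deg_log2fc = deg_log2fc,
              nb_dispersion = nb_dispersion, mean_expr = mean_expr)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed", x$seed, ")\n")
  cat(sprintf("  %d groups x %d replicates: %s\n", x$n_groups, x$n_per_group,
              paste(x$group_names, collapse = ", ")))
  cat(sprintf("  genome: %d chromosome(s) of %d bp, %d genes, %.0f CpG/kb\n",
              x$n_chroms, x$chrom_length, x$n_genes, x$cpg_rate))
  cat(sprintf("  planted: %d DMRs (delta %.2f, %d-%d bp), %d DEGs (|log2FC| %.2f)\n",
              x$n_dmrs, x$dmr_delta, x$dmr_len_range[1], x$dmr_len_range[2],
              x$n_degs, x$deg_log2fc))
  invisible(x)
}
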