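#' Simulate multi-group bisulfite cytosine reports with planted DMRs
#'
#' Draws cytosine sites along the toy genome (symmetric CpG pairs plus a small
#' fraction of CHG/CHH cytosines), assigns each site a true methylation level
#' from the feature it falls in, plants differentially methylated regions for
#' designated group pairs, and samples per-sample counts: depth from a negative
#' binomial, methylated counts from a beta-binomial with the configured site
#' dispersion. An unmethylated spike-in control chromosome is emitted whose
#' only methylated calls come from bisulfite conversion failure. Output rows
#' follow the Bismark CX-report dialect (1-based position; chrom, pos, strand,
#' methylated count, unmethylated count, context, trinucleotide; no header).
#'
#' @param config a [sim_config()] object.
#' @param catalog a `feature_catalog` from [build_toy_annotation()].
#' @param out_dir optional directory; when given, one `<sample>.CX_report.txt`
#'   per sample plus `truth_dmrs.tsv` and `samples.tsv` are written.
#' @return a list of class `meth_sim` with elements `reports` (named list of
#'   per-sample cytosine-report data frames), `samples` (data.frame sample,
#'   group), and `truth` (data.frame of planted DMRs: chrom, start, end,
#'   group_a, group_b, delta = realised mean methylation difference
#'   group_a - group_b over member CpG sites, context, n_sites).
#' @export
simulate_methylome <- function(config, catalog, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "feature_catalog"))
  set.seed(stage_seed(config$seed, "methylome"))
  chroms <- names(catalog$chrom_sizes)

  sites <- do.call(rbind, lapply(chroms, function(ch) {
    len <- catalog$chrom_sizes[[ch]]
    n_cpg <- max(1L, round(config$cpg_rate / 1000 * len))
    cpg_pos <- sort(sample.int(len - 2L, min(len %/% 3L, 2L * n_cpg)))
    cpg_pos <- cpg_pos[c(TRUE, diff(cpg_pos) >= 2L)]  # CpGs cannot overlap
    cpg_pos <- sort(sample(cpg_pos, min(n_cpg, length(cpg_pos))))
    n_cpg <- length(cpg_pos)
    h <- c("A", "C", "T")
    cg <- data.frame(chrom = ch,
                     pos = as.integer(c(rbind(cpg_pos, cpg_pos + 1L))),
                     strand = rep(c("+", "-"), n_cpg),
                     context = "CG",
                     tri = paste0("CG", sample(c("A", "C", "G", "T"), 2L * n_cpg,
                                               replace = TRUE)))
    n_non <- round(config$frac_chh_chg / (1 - config$frac_chh_chg) * nrow(cg))
    non <- NULL
    if (n_non > 0L) {
      npos <- sort(sample(setdiff(seq_len(len), c(cpg_pos, cpg_pos + 1L)), n_non))
      ctx <- sample(c("CHG", "CHH"), n_non, replace = TRUE, prob = c(0.3, 0.7))
      non <- data.frame(chrom = ch, pos = npos,
                        strand = sample(c("+", "-"), n_non, replace = TRUE),
                        context = ctx,
                        tri = ifelse(ctx == "CHG",
                                     paste0("C", sample(h, n_non, TRUE), "G"),
                                     paste0("C", sample(h, n_non, TRUE),
                                            sample(h, n_non, TRUE))))
    }
    out <- rbind(cg, non)
    out[order(out$pos), ]
  }))
  rownames(sites) <- NULL

  # true methylation level: feature-priority lookup (CGI wins over promoter,
  # promoter over UTRs, gene parts over repeats/intergenic)
  bm <- config$baseline_meth_by_feature
  mu <- rep(bm$intergenic, nrow(sites))
  gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  for (feat in c("repeats", "introns", "exons", "utr3", "utr5", "shores",
                 "promoters", "cgi")) {
    key <- c(repeats = "repeat", introns = "intron", exons = "exon",
             utr3 = "utr3", utr5 = "utr5", shores = "shore",
             promoters = "promoter", cgi = "cgi")[[feat]]
    hit <- IRanges::overlapsAny(gr, catalog[[feat]], ignore.strand = TRUE)
    mu[hit] <- bm[[key]]
  }
  mu[sites$context != "CG"] <- bm$non_cg

  groups <- rep(config$group_names, each = config$n_per_group)
  sample_ids <- paste0(rep(config$group_names, each = config$n_per_group), "_",
                       rep(seq_len(config$n_per_group), config$n_groups))

  # plant DMRs: non-overlapping intervals, group pairs cycled; a fraction is
  # shared by a second pair to emulate recurrently affected genes
  mu_by_group <- matrix(mu, nrow = nrow(sites), ncol = config$n_groups,
                        dimnames = list(NULL, config$group_names))
  truth <- data.frame()
  if (config$n_dmrs > 0L) {
    placed <- GenomicRanges::GRanges()
    n_pairs <- length(config$dmr_pairs)
    for (d in seq_len(config$n_dmrs)) {
      len <- sample1(seq(config$dmr_len_range[1], config$dmr_len_range[2]))
      ok <- FALSE
      for (try in 1:200) {
        ch <- sample(chroms, 1L)
        s <- sample.int(catalog$chrom_sizes[[ch]] - len, 1L)
        cand <- GenomicRanges::GRanges(factor(ch, levels = chroms),
                                       IRanges::IRanges(s, s + len - 1L))
        idx <- which(sites$chrom == ch & sites$pos >= s & sites$pos <= s + len - 1L &
                       sites$context == "CG")
        if (length(idx) >= 3L &&
            (length(placed) == 0L ||
             !any(IRanges::overlapsAny(cand, placed + 1000L)))) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf("could not place planted DMR %d (length %d bp) without collision",
                     d, len))
      placed <- c(placed, cand)
      pairs <- list(config$dmr_pairs[[(d - 1L) %% n_pairs + 1L]])
      if (n_pairs > 1L && runif(1) < config$dmr_share_frac)
        pairs <- c(pairs, list(config$dmr_pairs[[d %% n_pairs + 1L]]))
      sgn <- if (d %% 2L == 0L) -1 else 1
      for (pr in pairs) {
        # keep the full |delta| by shifting away from the nearer boundary
        # when the requested direction would saturate at 0/1
        mu_here <- mu_by_group[idx, pr[2]]
        if (mean(mu_here) - sgn * config$dmr_delta < 0.02 ||
            mean(mu_here) - sgn * config$dmr_delta > 0.98)
          sgn <- -sgn
        shifted <- clip(mu_here - sgn * config$dmr_delta, 0.02, 0.98)
        mu_by_group[idx, pr[2]] <- shifted
        truth <- rbind(truth, data.frame(
          chrom = ch, start = s, end = s + len - 1L,
          group_a = pr[1], group_b = pr[2],
          delta = mean(mu_by_group[idx, pr[1]] - shifted),
          context = "CG", n_sites = length(idx)))
      }
    }
  }

  phi <- config$site_dispersion
  reports <- lapply(seq_along(sample_ids), function(si) {
    n <- rnbinom(nrow(sites), size = config$coverage_dispersion,
                 mu = config$coverage_mean)
    m_true <- mu_by_group[, groups[si]]
    p <- if (phi > 0) {
      a <- m_true * (1 / phi - 1); b <- (1 - m_true) * (1 / phi - 1)
      rbeta(nrow(sites), a, b)
    } else m_true
    p_obs <- p + (1 - p) * config$conversion_failure
    m <- rbinom(nrow(sites), n, p_obs)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               count_methylated = m, count_unmethylated = n - m,
               context = sites$context, trinucleotide = sites$tri)
  })
  names(reports) <- sample_ids

  # spike-in control chromosome: truly unmethylated cytosines, methylated
  # reads arise only from conversion failure
  n_ctrl <- round(2 * config$control_site_rate * config$control_chrom_length)
  if (n_ctrl > 0L) {
    cpos <- sort(sample.int(config$control_chrom_length, n_ctrl, replace = FALSE))
    cctx <- sample(c("CG", "CHG", "CHH"), n_ctrl, replace = TRUE,
                   prob = c(0.1, 0.2, 0.7))
    h <- c("A", "C", "T")
    ctrl_sites <- data.frame(
      chrom = config$control_chrom, pos = cpos,
      strand = sample(c("+", "-"), n_ctrl, replace = TRUE),
      context = cctx,
      tri = ifelse(cctx == "CG",
                   paste0("CG", sample(c("A", "C", "G", "T"), n_ctrl, TRUE)),
                   ifelse(cctx == "CHG", paste0("C", sample(h, n_ctrl, TRUE), "G"),
                          paste0("C", sample(h, n_ctrl, TRUE), sample(h, n_ctrl, TRUE)))))
    for (si in seq_along(sample_ids)) {
      n <- rnbinom(n_ctrl, size = config$coverage_dispersion,
                   mu = config$coverage_mean)
      m <- rbinom(n_ctrl, n, config$conversion_failure)
      reports[[si]] <- rbind(reports[[si]], data.frame(
        chrom = ctrl_sites$chrom, pos = ctrl_sites$pos,
        strand = ctrl_sites$strand, count_methylated = m,
        count_unmethylated = n - m, context = ctrl_sites$context,
        trinucleotide = ctrl_sites$tri))
    }
  }

  samples <- data.frame(sample = sample_ids, group = groups)
  sim <- structure(list(reports = reports, samples = samples, truth = truth,
                        config = config),
                   class = "meth_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sample_ids)
      write_cytosine_report(reports[[s]],
                            file.path(out_dir, paste0(s, ".CX_report.txt")))
    write.table(truth, file.path(out_dir, "truth_dmrs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  sim
}

#' @export
print.meth_sim <- function(x, ...) {
  cat("Simulated methylome:", length(x$reports), "samples,",
      nrow(x$reports[[1]]), "cytosine rows each;",
      nrow(x$truth), "planted DMR records\n")
  invisible(x)
}
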