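#' Pipeline run configuration
#'
#' Collects the simulation configuration and every stage parameter of the
#' end-to-end run. Any element can be overridden; the result can also be
#' loaded from / saved to YAML.
#'
#' @param seed master seed for the run; every stochastic stage derives its
#'   substream from it.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param contrasts list of group pairs to compare; default all pairwise.
#' @param min_depth,fdr site-calling thresholds.
#' @param window,p_threshold,min_len,min_sites,pct_sig,merge_gap DMR-calling
#'   parameters.
#' @param alpha,lfc DEG thresholds (Bonferroni-adjusted p, |log2FC|).
#' @param flank gene-association flank (bp).
#' @param eps pseudo-fraction in the DMR methylation log2FC.
#' @param dmr_contexts contexts tested for DMRs.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = NULL, contrasts = NULL,
                       min_depth = 5L, fdr = 0.01, window = 500L,
                       p_threshold = 1e-5, min_len = 50L, min_sites = 3L,
                       pct_sig = 0.5, merge_gap = 100L, alpha = 0.05,
                       lfc = 1.0, flank = 1000L, eps = 0.01,
                       dmr_contexts = "CG") {
  sim <- sim %||% sim_config(seed = seed)
  if (is.null(contrasts)) {
    cb <- combn(sim$group_names, 2L)
    contrasts <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  structure(list(seed = as.integer(seed), sim = sim, contrasts = contrasts,
                 min_depth = min_depth, fdr = fdr, window = window,
                 p_threshold = p_threshold, min_len = min_len,
                 min_sites = min_sites, pct_sig = pct_sig,
                 merge_gap = merge_gap, alpha = alpha, lfc = lfc,
                 flank = flank, eps = eps, dmr_contexts = dmr_contexts),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `sim` block mirrors
#' [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- y$seed %||% 1L
  y$sim <- do.call(sim_config, sim_args)
  if (!is.null(y$contrasts)) y$contrasts <- lapply(y$contrasts, unlist)
  do.call(run_config, y)
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate, call-sites, annotate, call-dmrs, call-degs and integrate
#' in dependency order, writing each stage's outputs plus `manifest.json`
#' (stage parameters, output files and their MD5 hashes) under `out_dir`.
#' Stages never mutate their inputs; a rerun with the same configuration
#' recomputes everything and, for a fixed seed, reproduces every table
#' byte-identically.
#'
#' @param config a `run_config`, or path to a YAML file.
#' @param out_dir output directory.
#' @return list of in-memory stage results (invisible file layout documented
#'   in the manifest), of class `pipeline_run`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, params, files) {
    files <- files[file.exists(files)]
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, parameters = params,
      outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  }
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  log_msg("stage simulate: toy annotation, methylome, expression")
  sim_dir <- file.path(out_dir, "sim")
  catalog <- build_toy_annotation(config$sim, out_dir = sim_dir)
  msim <- simulate_methylome(config$sim, catalog, out_dir = sim_dir)
  esim <- simulate_expression(config$sim, catalog, out_dir = sim_dir)
  note("simulate", list(seed = config$sim$seed),
       list.files(sim_dir, full.names = TRUE))

  log_msg("stage call-sites: binomial tests in ", length(msim$reports), " samples")
  site_dir <- file.path(out_dir, "sites")
  dir.create(site_dir, showWarnings = FALSE)
  calls <- lapply(msim$reports, call_true_methylated,
                  min_depth = config$min_depth, fdr = config$fdr)
  conv <- sapply(names(calls), function(s) {
    ctl <- msim$reports[[s]]
    conversion_rate(ctl[ctl$chrom == config$sim$control_chrom, ])
  })
  for (s in names(calls)) {
    write.table(calls[[s]], file.path(site_dir, paste0(s, ".calls.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(calls[[s]], file.path(site_dir, paste0(s, ".bedGraph")))
  }
  write.table(data.frame(sample = names(conv), conversion_rate_pct = conv),
              file.path(site_dir, "conversion_rates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("call-sites", list(min_depth = config$min_depth, fdr = config$fdr),
       list.files(site_dir, full.names = TRUE))

  log_msg("stage annotate: feature methylation profile and group statistics")
  ann_dir <- file.path(out_dir, "annotation")
  dir.create(ann_dir, showWarnings = FALSE)
  genomic_calls <- lapply(calls, function(cl)
    cl[cl$chrom != config$sim$control_chrom, ])
  profile <- feature_methylation_profile(genomic_calls, catalog,
                                         min_depth = config$min_depth)
  write.table(profile, file.path(ann_dir, "feature_methylation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  groups_map <- setNames(msim$samples$group, msim$samples$sample)
  stats_rep <- suppressWarnings(group_stats(profile, groups_map))
  write.table(stats_rep$dunn, file.path(ann_dir, "dunn_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(stats_rep$anova, file.path(ann_dir, "anova.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("annotate", list(min_depth = config$min_depth),
       list.files(ann_dir, full.names = TRUE))

  dmr_dir <- file.path(out_dir, "dmr"); dir.create(dmr_dir, showWarnings = FALSE)
  de_dir <- file.path(out_dir, "de"); dir.create(de_dir, showWarnings = FALSE)
  int_dir <- file.path(out_dir, "integration")
  dir.create(int_dir, showWarnings = FALSE)
  dmr_sets <- list(); de_sets <- list(); integrations <- list()
  for (ct in config$contrasts) {
    tag <- paste0(ct[1], "_vs_", ct[2])
    log_msg("stage call-dmrs: ", tag)
    st <- dmr_site_tests(msim$reports, msim$samples, ct,
                         window = config$window,
                         contexts = config$dmr_contexts,
                         control_chrom = config$sim$control_chrom)
    dmrs <- call_dmrs(st, p_threshold = config$p_threshold,
                      min_len = config$min_len, min_sites = config$min_sites,
                      pct_sig = config$pct_sig, merge_gap = config$merge_gap)
    write.table(dmrs, file.path(dmr_dir, paste0(tag, ".dmrs.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dmr_sets[[tag]] <- dmrs

    log_msg("stage call-degs: ", tag)
    de <- de_test(esim$counts, esim$samples$group, ct, alpha = config$alpha,
                  lfc = config$lfc)
    write.table(de, file.path(de_dir, paste0(tag, ".de.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    de_sets[[tag]] <- de

    log_msg("stage integrate: ", tag)
    rec <- overlap_deg_dmr(de, dmrs, catalog,
                           comparison = paste(ct, collapse = " vs "),
                           flank = config$flank, eps = config$eps)
    write.table(rec, file.path(int_dir, paste0(tag, ".integration.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    integrations[[tag]] <- rec
  }
  note("call-dmrs", list(p_threshold = config$p_threshold,
                         window = config$window),
       list.files(dmr_dir, full.names = TRUE))
  note("call-degs", list(alpha = config$alpha, lfc = config$lfc),
       list.files(de_dir, full.names = TRUE))
  note("integrate", list(flank = config$flank, eps = config$eps),
       list.files(int_dir, full.names = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(list(catalog = catalog, methylome = msim,
                           expression = esim, calls = calls,
                           conversion = conv, profile = profile,
                           stats = stats_rep, dmrs = dmr_sets, de = de_sets,
                           integration = integrations, out_dir = out_dir,
                           config = config),
                      class = "pipeline_run"))
}

#' Summarise a pipeline run directory
#'
#' Builds a plain-text report of the run: conversion rates, context breakdown
#' inputs, feature methylation, DMR descriptors, DEG counts and the
#' concordance table, each read back from the stage TSVs. Stages with no
#' outputs are reported as empty rather than failing. With
#' `table1_only = TRUE` the report contains just the concordance-count
#' section computed from the packaged reference overlap table.
#'
#' @param run_dir directory written by [run_pipeline()] (ignored when
#'   `table1_only`).
#' @param table1_only report concordance counts of the packaged reference
#'   table instead of a run (default FALSE).
#' @return character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(run_dir = NULL, table1_only = FALSE) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  concord_section <- function(records, source_name) {
    add("## Methylation-expression concordance (", source_name, ")")
    for (cmp in unique(records$comparison)) {
      up <- count_concordant_genes(records, cmp, "up")
      dn <- count_concordant_genes(records, cmp, "down")
      add(sprintf("%s: %d concordant genes with higher expression at the first stage, %d with lower",
                  cmp, up$n, dn$n))
    }
  }
  if (table1_only) {
    concord_section(read_table1(), "reference overlap table")
  } else {
    stopifnot(dir.exists(run_dir))
    conv_path <- file.path(run_dir, "sites", "conversion_rates.tsv")
    if (file.exists(conv_path)) {
      cv <- read.table(conv_path, header = TRUE, sep = "\t")
      add("## Bisulfite conversion");
      add(sprintf("mean conversion rate %.2f%% over %d samples",
                  mean(cv$conversion_rate_pct), nrow(cv)))
    } else add("## Bisulfite conversion", "no call-sites outputs")
    dmr_files <- list.files(file.path(run_dir, "dmr"), full.names = TRUE)
    add("## Differentially methylated regions")
    if (length(dmr_files) == 0L) add("no call-dmrs outputs")
    for (f in dmr_files) {
      d <- read.table(f, header = TRUE, sep = "\t")
      add(sprintf("%s: %d DMRs%s", basename(f), nrow(d),
                  if (nrow(d)) sprintf(", median length %d bp, mean %.1f sites",
                                       as.integer(median(d$length)),
                                       mean(d$n_sites)) else ""))
    }
    de_files <- list.files(file.path(run_dir, "de"), full.names = TRUE)
    add("## Differentially expressed genes")
    if (length(de_files) == 0L) add("no call-degs outputs")
    for (f in de_files) {
      d <- read.table(f, header = TRUE, sep = "\t")
      add(sprintf("%s: %d DEGs of %d tested", basename(f),
                  sum(d$is_deg, na.rm = TRUE), sum(!is.na(d$p_value))))
    }
    int_files <- list.files(file.path(run_dir, "integration"), full.names = TRUE)
    if (length(int_files)) {
      recs <- do.call(rbind, lapply(int_files, function(f)
        read.table(f, header = TRUE, sep = "\t")))
      if (nrow(recs)) concord_section(recs, "this run") else
        add("## Methylation-expression concordance", "no overlapping genes")
    } else add("## Methylation-expression concordance", "no integrate outputs")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run in", x$out_dir, "\n")
  cat("  contrasts:", paste(sapply(x$config$contrasts, paste, collapse = " vs "),
                            collapse = "; "), "\n")
  cat("  DMRs:", paste(names(x$dmrs), sapply(x$dmrs, nrow), sep = "=",
                       collapse = " "), "\n")
  cat("  DEGs:", paste(names(x$de), sapply(x$de, function(d) sum(d$is_deg)),
                       sep = "=", collapse = " "), "\n")
  invisible(x)
}
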