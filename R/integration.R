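#' Load the packaged DEG-DMR overlap reference table
#'
#' A verbatim copy of the published overlap table between differentially
#' expressed genes and genes carrying DMRs across gestational comparisons:
#' one row per (gene, DMR, region) with expression and methylation log2 fold
#' changes, context, region label, comparison and the printed agreement call
#' (Yes / No / "No *", the latter marking a positive gene-body
#' methylation-expression correlation). The `flag` column marks the two
#' promoter rows whose printed call departs from the sign rule because the
#' positive-correlation footnote applies to gene-body regions only.
#'
#' @return data.frame with columns gene_id, gene_name, chrom,
#'   log2fc_expression, log2fc_methylation, context, region, comparison,
#'   agreement, flag.
#' @export
read_table1 <- function() {
  path <- system.file("extdata", "table1_dmr_deg_overlap.tsv",
                      package = "methdyn", mustWork = TRUE)
  d <- read.table(path, sep = "\t", header = TRUE, quote = "", fill = TRUE,
                  colClasses = "character", check.names = FALSE)
  d$log2fc_expression <- as.numeric(d$log2fc_expression)
  d$log2fc_methylation <- as.numeric(d$log2fc_methylation)
  d$flag[is.na(d$flag)] <- ""
  d
}

#' Classify methylation-expression agreement
#'
#' concordant: the fold changes have strictly opposite signs (the canonical
#' repressive pattern: lower methylation with higher expression or vice
#' versa). discordant_positive: both strictly positive (methylation and
#' expression rise together). discordant_other: anything else, including both
#' strictly negative and exact zeros.
#'
#' @param log2fc_expression,log2fc_methylation numeric (vectorised).
#' @return character vector of agreement classes.
#' @export
classify_agreement <- function(log2fc_expression, log2fc_methylation) {
  e <- sign(log2fc_expression); m <- sign(log2fc_methylation)
  ifelse(e != 0 & m != 0 & e == -m, "concordant",
         ifelse(e > 0 & m > 0, "discordant_positive", "discordant_other"))
}

#' Overlap DEGs with DMR-carrying genes for one comparison
#'
#' Produces one record per (DEG gene x overlapping DMR x region label). Genes
#' lacking either a DEG call or a DMR are absent. Methylation log2FC comes
#' from [dmr_methylation_log2fc()] on the DMR's raw group means; agreement
#' from [classify_agreement()].
#'
#' @param degs a `de_result` with is_deg (see [call_degs()]).
#' @param dmrs a `dmr_set`.
#' @param catalog a `feature_catalog` (for gene association and region labels).
#' @param comparison label such as "4M vs 6M"; must match both inputs'
#'   contrast attributes when present.
#' @param flank gene-association flank in bp (default 1000).
#' @param eps pseudo-fraction for the methylation log2FC (default 0.01).
#' @return data.frame of class `integration_records`: gene_id, gene_name,
#'   chrom, log2fc_expression, log2fc_methylation, context, region,
#'   comparison, agreement, dmr_start, dmr_end.
#' @export
overlap_deg_dmr <- function(degs, dmrs, catalog, comparison, flank = 1000L,
                            eps = 0.01) {
  lab <- function(x) paste(attr(x, "contrast"), collapse = " vs ")
  for (obj in list(degs, dmrs)) {
    if (!is.null(attr(obj, "contrast")) && lab(obj) != comparison)
      stop(sprintf("comparison label mismatch: '%s' vs input '%s'",
                   comparison, lab(obj)))
  }
  empty <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), log2fc_expression = numeric(0),
                      log2fc_methylation = numeric(0), context = character(0),
                      region = character(0), comparison = character(0),
                      agreement = character(0), dmr_start = integer(0),
                      dmr_end = integer(0))
  deg_tab <- degs[degs$is_deg %in% TRUE, ]
  if (nrow(deg_tab) == 0L || nrow(dmrs) == 0L) {
    class(empty) <- c("integration_records", "data.frame")
    return(empty)
  }
  reg <- region_labels(dmrs, catalog, flank = flank)
  reg <- reg[reg$gene_id %in% deg_tab$gene_id, ]
  if (nrow(reg) == 0L) {
    class(empty) <- c("integration_records", "data.frame")
    return(empty)
  }
  gn <- catalog$genes$gene_name[match(reg$gene_id, catalog$genes$gene_id)]
  meth_lfc <- dmr_methylation_log2fc(dmrs, eps = eps)[reg$query]
  expr_lfc <- deg_tab$log2fc[match(reg$gene_id, deg_tab$gene_id)]
  out <- data.frame(gene_id = reg$gene_id,
                    gene_name = ifelse(is.na(gn), reg$gene_id, gn),
                    chrom = dmrs$chrom[reg$query],
                    log2fc_expression = expr_lfc,
                    log2fc_methylation = meth_lfc,
                    context = dmrs$context[reg$query],
                    region = reg$region,
                    comparison = comparison,
                    agreement = classify_agreement(expr_lfc, meth_lfc),
                    dmr_start = dmrs$start[reg$query],
                    dmr_end = dmrs$end[reg$query])
  rownames(out) <- NULL
  class(out) <- c("integration_records", "data.frame")
  out
}

#' Count unique concordant genes in a comparison and direction
#'
#' @param records integration records (or the reference table with columns
#'   comparison, agreement or log2fc columns).
#' @param comparison comparison label, e.g. "4M vs 6M".
#' @param direction "up" (expression log2FC > 0) or "down" (< 0).
#' @return list: `n` unique gene count, `genes` sorted unique gene keys
#'   (gene_id, falling back to gene_name where the id is missing).
#' @export
count_concordant_genes <- function(records, comparison, direction = c("up", "down")) {
  direction <- match.arg(direction)
  agree <- if ("agreement" %in% names(records) &&
               all(records$agreement %in% c("concordant", "discordant_positive",
                                            "discordant_other")))
    records$agreement else
      classify_agreement(records$log2fc_expression, records$log2fc_methylation)
  keep <- records$comparison == comparison & agree == "concordant" &
    (if (direction == "up") records$log2fc_expression > 0 else
       records$log2fc_expression < 0)
  r <- records[keep, , drop = FALSE]
  key <- r$gene_id
  if (!is.null(r$gene_name))
    key <- ifelse(is.na(key) | key == "", r$gene_name, key)
  genes <- sort(unique(key))
  list(n = length(genes), genes = genes)
}

#' Region-label distribution of records
#'
#' @param records integration records (typically the concordant subset).
#' @return named percentages over region labels, summing to 100.
#' @export
region_distribution <- function(records) {
  if (nrow(records) == 0L) return(numeric(0))
  tab <- table(records$region)
  100 * as.vector(tab) / sum(tab) -> pct
  sort(setNames(pct, names(tab)), decreasing = TRUE)
}

#' Genes recurrently affected across comparisons
#'
#' @param gene_sets named list of gene-id vectors, one per comparison.
#' @param k minimum number of comparisons (default 2).
#' @return sorted character vector of genes present in at least k sets.
#' @export
recurrent_dmr_genes <- function(gene_sets, k = 2L) {
  all_genes <- unlist(lapply(gene_sets, unique))
  tab <- table(all_genes)
  sort(names(tab)[tab >= k])
}

#' @export
print.integration_records <- function(x, ...) {
  cat("DEG-DMR integration:", nrow(x), "records,",
      length(unique(x$gene_id)), "genes;",
      sum(x$agreement == "concordant"), "concordant record(s)\n")
  invisible(x)
}
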