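#' Load a genome annotation into a feature catalog
#'
#' Imports gene models from GTF/GFF (records of type gene, exon,
#' five_prime_utr, three_prime_utr carrying a gene_id attribute), CpG island
#' and repeat intervals from BED, and chromosome sizes from a two-column
#' table. Promoters (1 kb upstream of the TSS through the TSS, strand-aware),
#' introns (gene span minus exons) and CGI shores (2 kb flanks clipped at
#' neighbouring CGIs and chromosome ends) are derived.
#'
#' @param gtf_path GTF/GFF file of gene models.
#' @param cgi_bed,repeat_bed BED files of CpG islands and repeats.
#' @param chrom_sizes_path two-column chrom.sizes table.
#' @return a `feature_catalog` (see [build_toy_annotation()]).
#' @export
load_annotation <- function(gtf_path, cgi_bed, repeat_bed, chrom_sizes_path) {
  chrom_sizes <- read_chrom_sizes(chrom_sizes_path)
  si <- GenomeInfoDb::Seqinfo(names(chrom_sizes), chrom_sizes)
  gtf <- rtracklayer::import(gtf_path)
  if (is.null(gtf$type) || is.null(gtf$gene_id))
    stop("GTF must carry 'type' and 'gene_id' attributes")
  pick <- function(type) {
    gr <- gtf[gtf$type == type]
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(chrom_sizes)) |
      GenomicRanges::end(gr) > chrom_sizes[as.character(GenomicRanges::seqnames(gr))] |
      GenomicRanges::start(gr) < 1
    if (any(bad))
      stop(sprintf("%d %s record(s) outside chromosome bounds, first at %s:%d-%d",
                   sum(bad), type,
                   as.character(GenomicRanges::seqnames(gr))[which(bad)[1]],
                   GenomicRanges::start(gr)[which(bad)[1]],
                   GenomicRanges::end(gr)[which(bad)[1]]))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(GenomicRanges::start(gr),
                                                   GenomicRanges::end(gr)),
                                  strand = GenomicRanges::strand(gr), seqinfo = si)
    out$gene_id <- gr$gene_id
    out$gene_name <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    out
  }
  genes <- pick("gene")
  exons <- pick("exon")
  utr5 <- pick("five_prime_utr")
  utr3 <- pick("three_prime_utr")
  import_bed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::IRanges(GenomicRanges::start(gr),
                                            GenomicRanges::end(gr)),
                           seqinfo = si)
  }
  cgi <- import_bed(cgi_bed)
  repeats <- import_bed(repeat_bed)
  structure(list(chrom_sizes = chrom_sizes, genes = genes, exons = exons,
                 introns = derive_introns(genes, exons), utr5 = utr5,
                 utr3 = utr3, promoters = derive_promoters(genes, chrom_sizes),
                 cgi = cgi, shores = derive_shores(cgi, chrom_sizes),
                 repeats = repeats),
            class = "feature_catalog")
}

as_query_granges <- function(query) {
  if (is(query, "GRanges")) return(query)
  if (is.data.frame(query)) {
    end <- if ("end" %in% names(query)) query$end else query$pos
    start <- if ("start" %in% names(query)) query$start else query$pos
    return(GenomicRanges::GRanges(query$chrom, IRanges::IRanges(start, end)))
  }
  stop("query must be a GRanges or a data.frame with chrom/start/end (or pos)")
}

#' Associate intervals with genes by the 1 kb TSS/TTS rule
#'
#' A query is associated with every gene whose span, extended by `flank` bp on
#' both ends (i.e. 1 kb upstream of the TSS and 1 kb downstream of the TTS),
#' intersects it. Multiple genes may be returned per query.
#'
#' @param query GRanges or data.frame with chrom, start, end.
#' @param catalog a `feature_catalog`.
#' @param flank association flank in bp (default 1000).
#' @return data.frame with columns query (row index) and gene_id.
#' @export
associate_gene <- function(query, catalog, flank = 1000L) {
  q <- as_query_granges(query)
  if (length(catalog$genes) == 0L || length(q) == 0L)
    return(data.frame(query = integer(0), gene_id = character(0)))
  ext <- catalog$genes
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(ext) - flank)
  GenomicRanges::end(ext) <- GenomicRanges::end(ext) + flank
  hits <- GenomicRanges::findOverlaps(q, ext, ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             gene_id = ext$gene_id[S4Vectors::subjectHits(hits)])
}

feature_vocabulary <- c("cgi", "shore", "promoter", "utr5", "utr3", "exon",
                        "intron", "repeat")

#' Assign genomic feature labels to intervals
#'
#' Returns every feature label an interval intersects (multi-label; a query
#' spanning an exon-intron junction counts under both). An empty label set
#' means intergenic. With `priority = TRUE` only the highest-priority label is
#' kept (promoter > utr5 > exon > utr3 > intron > repeat > shore > cgi).
#'
#' @param query GRanges or data.frame with chrom, start, end.
#' @param catalog a `feature_catalog`.
#' @param priority single-label mode (default FALSE, multi-label).
#' @return data.frame with columns query (row index) and feature.
#' @export
assign_features <- function(query, catalog, priority = FALSE) {
  q <- as_query_granges(query)
  slots <- c(cgi = "cgi", shore = "shores", promoter = "promoters",
             utr5 = "utr5", utr3 = "utr3", exon = "exons", intron = "introns",
             `repeat` = "repeats")
  out <- do.call(rbind, lapply(names(slots), function(lbl) {
    gr <- catalog[[slots[[lbl]]]]
    if (length(gr) == 0L) return(NULL)
    hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
    if (length(hits) == 0L) return(NULL)
    data.frame(query = unique(S4Vectors::queryHits(hits)), feature = lbl)
  }))
  if (is.null(out)) out <- data.frame(query = integer(0), feature = character(0))
  if (priority && nrow(out) > 0L) {
    ord <- c("promoter", "utr5", "exon", "utr3", "intron", "repeat", "shore", "cgi")
    out <- out[order(out$query, match(out$feature, ord)), ]
    out <- out[!duplicated(out$query), ]
  }
  rownames(out) <- NULL
  out
}

#' Per-feature, per-sample methylation percentages
#'
#' For each of the eight feature classes and each sample, the unweighted mean
#' of per-site methylation fractions over tested sites (depth >= min_depth)
#' inside the feature, times 100. Features with no tested sites get NA (absence
#' of evidence is not 0% methylation). Control-chromosome sites (chromosomes
#' absent from the catalog) are excluded.
#'
#' @param calls_list named list of `site_calls`, one per sample.
#' @param catalog a `feature_catalog`.
#' @param min_depth depth threshold for inclusion (default 5).
#' @return long data.frame: feature, sample, meth_pct, n_sites.
#' @export
feature_methylation_profile <- function(calls_list, catalog, min_depth = 5L) {
  slots <- c(cgi = "cgi", shore = "shores", promoter = "promoters",
             utr5 = "utr5", utr3 = "utr3", exon = "exons", intron = "introns",
             `repeat` = "repeats")
  out <- list()
  for (s in names(calls_list)) {
    cl <- calls_list[[s]]
    cl <- cl[cl$depth >= min_depth & cl$chrom %in% names(catalog$chrom_sizes), ]
    gr <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$pos, cl$pos))
    for (lbl in names(slots)) {
      feat <- catalog[[slots[[lbl]]]]
      inside <- if (length(feat)) IRanges::overlapsAny(gr, feat,
                                                             ignore.strand = TRUE)
                else rep(FALSE, length(gr))
      vals <- cl$meth_fraction[inside]
      out[[length(out) + 1L]] <- data.frame(
        feature = lbl, sample = s,
        meth_pct = if (length(vals)) 100 * mean(vals) else NA_real_,
        n_sites = length(vals))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "weighting") <- "unweighted mean of per-site fractions"
  res
}

#' Region labels for gene-level integration
#'
#' For each (query, gene) association, returns the labels used in
#' methylome-transcriptome overlap tables: Promoter, Utr5, Utr3, Exon, Intron
#' when the query overlaps that gene's feature, plus TSS / TES when it
#' overlaps the transcription start / termination site +/- `flank` bp.
#'
#' @param query GRanges or data.frame with chrom, start, end.
#' @param catalog a `feature_catalog`.
#' @param flank TSS/TES window half-width (default 1000).
#' @return data.frame: query (row index), gene_id, region.
#' @export
region_labels <- function(query, catalog, flank = 1000L) {
  q <- as_query_granges(query)
  assoc <- associate_gene(q, catalog, flank = flank)
  if (nrow(assoc) == 0L)
    return(data.frame(query = integer(0), gene_id = character(0),
                      region = character(0)))
  slots <- c(Promoter = "promoters", Utr5 = "utr5", Utr3 = "utr3",
             Exon = "exons", Intron = "introns")
  out <- list()
  for (lbl in names(slots)) {
    gr <- catalog[[slots[[lbl]]]]
    if (length(gr) == 0L) next
    hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    out[[lbl]] <- data.frame(query = S4Vectors::queryHits(hits),
                             gene_id = gr$gene_id[S4Vectors::subjectHits(hits)],
                             region = lbl)
  }
  genes <- catalog$genes
  if (length(genes)) {
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    tss <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
    tts <- ifelse(plus, GenomicRanges::end(genes), GenomicRanges::start(genes))
    for (lbl in c("TSS", "TES")) {
      anchor <- if (lbl == "TSS") tss else tts
      win <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                    IRanges::IRanges(pmax(1L, anchor - flank),
                                                     anchor + flank))
      hits <- GenomicRanges::findOverlaps(q, win, ignore.strand = TRUE)
      if (length(hits))
        out[[lbl]] <- data.frame(query = S4Vectors::queryHits(hits),
                                 gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                                 region = lbl)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(query = integer(0), gene_id = character(0), region = character(0))
  # keep only labels for genes the query is associated with
  key <- paste(res$query, res$gene_id)
  akey <- paste(assoc$query, assoc$gene_id)
  res <- res[key %in% akey, ]
  rownames(res) <- NULL
  res
}
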