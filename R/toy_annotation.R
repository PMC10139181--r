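#' Build a deterministic toy genome annotation
#'
#' Lays out non-overlapping multi-exon genes (with 5'/3' UTRs) across the
#' configured chromosomes, derives promoters and introns, places CpG islands
#' preferentially at promoters with 2 kb shores flanking them, and scatters
#' repeat intervals through intergenic space. All coordinates are 1-based
#' inclusive ([GenomicRanges::GRanges] convention).
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional directory; when given, the catalog is also written
#'   as `genes.gtf`, `cgi.bed`, `shores.bed`, `repeats.bed`, `promoters.bed`
#'   and `chrom.sizes` (see [write_catalog()]).
#' @return a `feature_catalog`: a list with `chrom_sizes` (named integer
#'   vector) and GRanges components `genes`, `exons`, `introns`, `utr5`,
#'   `utr3`, `promoters`, `cgi`, `shores`, `repeats`.
#' @export
build_toy_annotation <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)

  gene_rows <- list(); exon_rows <- list(); utr5_rows <- list(); utr3_rows <- list()
  cursor <- setNames(rep(1000L, length(chroms)), chroms)
  cur_chr <- 1L
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample(2:6, 1L)
    ex_len <- sample(120:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(300:1500, n_ex - 1L, replace = TRUE) else integer(0)
    footprint <- sum(ex_len) + sum(in_len)
    gap <- sample(2000:6000, 1L)
    placed <- FALSE
    for (try in seq_along(chroms)) {
      ch <- chroms[cur_chr]
      start <- cursor[ch] + gap
      if (start + footprint < chrom_sizes[ch] - 1000L) {
        placed <- TRUE
        break
      }
      cur_chr <- cur_chr %% length(chroms) + 1L
    }
    if (!placed)
      stop(sprintf(paste0("toy genome capacity exceeded at gene %d of %d: ",
                          "%d chromosome(s) of %d bp cannot hold the requested genes"),
                   g, config$n_genes, config$n_chroms, config$chrom_length))
    ends <- start + cumsum(ex_len) + cumsum(c(0L, in_len)) - 1L
    starts <- ends - ex_len + 1L
    gene_end <- ends[n_ex]
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("G%04d", g)
    gname <- sprintf("GENE%d", g)
    gene_rows[[g]] <- data.frame(chrom = ch, start = start, end = gene_end,
                                 strand = strand, gene_id = gid, gene_name = gname)
    exon_rows[[g]] <- data.frame(chrom = ch, start = starts, end = ends,
                                 strand = strand, gene_id = gid, gene_name = gname)
    # UTRs live at the outer ends of the terminal exons, strand-aware
    u5_len <- min(150L, ex_len[1] - 10L); u3_len <- min(200L, ex_len[n_ex] - 10L)
    if (strand == "+") {
      u5 <- c(start, start + u5_len - 1L)
      u3 <- c(gene_end - u3_len + 1L, gene_end)
    } else {
      u5 <- c(gene_end - u5_len + 1L, gene_end)
      u3 <- c(start, start + u3_len - 1L)
    }
    utr5_rows[[g]] <- data.frame(chrom = ch, start = u5[1], end = u5[2],
                                 strand = strand, gene_id = gid, gene_name = gname)
    utr3_rows[[g]] <- data.frame(chrom = ch, start = u3[1], end = u3[2],
                                 strand = strand, gene_id = gid, gene_name = gname)
    cursor[ch] <- gene_end
    cur_chr <- cur_chr %% length(chroms) + 1L
  }

  df2gr <- function(rows) {
    if (length(rows) == 0L)
      return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(chroms, chrom_sizes),
                                    gene_id = character(0), gene_name = character(0)))
    d <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                                 strand = d$strand,
                                 seqinfo = GenomeInfoDb::Seqinfo(chroms, chrom_sizes))
    gr$gene_id <- d$gene_id; gr$gene_name <- d$gene_name
    gr
  }
  genes <- df2gr(gene_rows)
  exons <- df2gr(exon_rows)
  utr5 <- df2gr(utr5_rows)
  utr3 <- df2gr(utr3_rows)
  promoters <- derive_promoters(genes, chrom_sizes)
  introns <- derive_introns(genes, exons)

  # CpG islands: most at promoters/TSS, a few intergenic
  cgi_list <- list()
  if (length(genes) > 0L) {
    tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                  GenomicRanges::start(genes), GenomicRanges::end(genes))
    at_prom <- runif(length(genes)) < 0.6
    for (i in which(at_prom)) {
      len <- sample(200:800, 1L)
      s <- max(1L, tss[i] - sample(0:300, 1L))
      cgi_list[[length(cgi_list) + 1L]] <-
        data.frame(chrom = as.character(GenomicRanges::seqnames(genes)[i]),
                   start = s, end = min(chrom_sizes[[1]], s + len - 1L))
    }
  }
  n_inter_cgi <- max(1L, config$n_genes %/% 10L)
  for (i in seq_len(n_inter_cgi)) {
    ch <- sample(chroms, 1L)
    len <- sample(200:800, 1L)
    s <- sample(seq_len(max(1L, chrom_sizes[ch] - len - 1L)), 1L)
    cgi_list[[length(cgi_list) + 1L]] <- data.frame(chrom = ch, start = s, end = s + len - 1L)
  }
  cgi <- GenomicRanges::reduce(GenomicRanges::GRanges(
    do.call(rbind, cgi_list)$chrom,
    IRanges::IRanges(do.call(rbind, cgi_list)$start, do.call(rbind, cgi_list)$end),
    seqinfo = GenomeInfoDb::Seqinfo(chroms, chrom_sizes)))
  shores <- derive_shores(cgi, chrom_sizes)

  # repeats in intergenic space (away from genes and their 1.5 kb flanks)
  genome_gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, chrom_sizes),
                                      seqinfo = GenomeInfoDb::Seqinfo(chroms, chrom_sizes))
  occupied <- if (length(genes)) GenomicRanges::resize(
    genes, GenomicRanges::width(genes) + 3000L, fix = "center") else genes
  intergenic <- GenomicRanges::setdiff(genome_gr, GenomicRanges::reduce(occupied),
                                       ignore.strand = TRUE)
  rep_list <- list()
  wide <- intergenic[GenomicRanges::width(intergenic) > 1000L]
  n_rep <- min(config$n_genes, 3L * length(wide))
  for (i in seq_len(n_rep)) {
    seg <- wide[sample(length(wide), 1L)]
    len <- sample(150:500, 1L)
    s <- GenomicRanges::start(seg) +
      sample(seq_len(GenomicRanges::width(seg) - len), 1L)
    rep_list[[i]] <- data.frame(chrom = as.character(GenomicRanges::seqnames(seg)),
                                start = s, end = s + len - 1L)
  }
  repeats <- if (length(rep_list)) GenomicRanges::reduce(GenomicRanges::GRanges(
    do.call(rbind, rep_list)$chrom,
    IRanges::IRanges(do.call(rbind, rep_list)$start, do.call(rbind, rep_list)$end),
    seqinfo = GenomeInfoDb::Seqinfo(chroms, chrom_sizes))) else
      GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(chroms, chrom_sizes))

  catalog <- structure(list(chrom_sizes = chrom_sizes, genes = genes,
                            exons = exons, introns = introns, utr5 = utr5,
                            utr3 = utr3, promoters = promoters, cgi = cgi,
                            shores = shores, repeats = repeats),
                       class = "feature_catalog")
  if (!is.null(out_dir)) write_catalog(catalog, out_dir)
  catalog
}

# promoter := 1 kb upstream of the TSS through the TSS, strand-aware,
# clipped at chromosome ends
derive_promoters <- function(genes, chrom_sizes) {
  if (length(genes) == 0L) return(genes)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  tss <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  s <- ifelse(plus, pmax(1L, tss - 1000L), tss)
  e <- ifelse(plus, tss,
              pmin(chrom_sizes[as.character(GenomicRanges::seqnames(genes))], tss + 1000L))
  pr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                               IRanges::IRanges(s, e),
                               strand = GenomicRanges::strand(genes),
                               seqinfo = GenomicRanges::seqinfo(genes))
  pr$gene_id <- genes$gene_id; pr$gene_name <- genes$gene_name
  pr
}

# introns := gene span minus its exons (per gene)
derive_introns <- function(genes, exons) {
  if (length(genes) == 0L) return(genes)
  out <- list()
  ex_by_gene <- split(exons, exons$gene_id)
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    ex <- ex_by_gene[[gid]]
    intr <- GenomicRanges::setdiff(genes[i], ex, ignore.strand = TRUE)
    if (length(intr) > 0L) {
      GenomicRanges::strand(intr) <- GenomicRanges::strand(genes[i])
      intr$gene_id <- gid; intr$gene_name <- genes$gene_name[i]
      out[[length(out) + 1L]] <- intr
    }
  }
  if (length(out) == 0L)
    return(GenomicRanges::GRanges(seqinfo = GenomicRanges::seqinfo(genes),
                                  gene_id = character(0), gene_name = character(0)))
  unlist(GenomicRanges::GRangesList(out))
}

# shores := 2 kb flanking each CGI, clipped at neighbouring CGIs and
# chromosome bounds
derive_shores <- function(cgi, chrom_sizes) {
  if (length(cgi) == 0L) return(cgi)
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(cgi),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(cgi) - 2000L),
                     pmin(chrom_sizes[as.character(GenomicRanges::seqnames(cgi))],
                          GenomicRanges::end(cgi) + 2000L)),
    seqinfo = GenomicRanges::seqinfo(cgi))
  GenomicRanges::setdiff(GenomicRanges::reduce(ext), cgi, ignore.strand = TRUE)
}

#' Write a feature catalog to disk
#'
#' Emits `genes.gtf` (gene/exon/UTR records), BED files for CGIs, shores,
#' repeats and promoters, and a two-column `chrom.sizes` table.
#'
#' @param catalog a `feature_catalog`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "feature_catalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- c(gtf_records(catalog$genes, "gene"),
           gtf_records(catalog$exons, "exon"),
           gtf_records(catalog$utr5, "five_prime_utr"),
           gtf_records(catalog$utr3, "three_prime_utr"))
  writeLines(gtf, file.path(dir, "genes.gtf"))
  for (nm in c("cgi", "shores", "repeats", "promoters")) {
    gr <- catalog[[nm]]
    names(gr) <- NULL
    rtracklayer::export(gr, file.path(dir, paste0(nm, ".bed")), format = "BED")
  }
  write.table(data.frame(names(catalog$chrom_sizes),
                         unname(catalog$chrom_sizes)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

gtf_records <- function(gr, type) {
  if (length(gr) == 0L) return(character(0))
  sprintf('%s\tmethdyn\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
          as.character(GenomicRanges::seqnames(gr)), type,
          GenomicRanges::start(gr), GenomicRanges::end(gr),
          as.character(GenomicRanges::strand(gr)),
          gr$gene_id, gr$gene_id, gr$gene_name)
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("Feature catalog:", length(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  cat(sprintf("  exons %d | introns %d | promoters %d | CGIs %d | shores %d | repeats %d\n",
              length(x$exons), length(x$introns), length(x$promoters),
              length(x$cgi), length(x$shores), length(x$repeats)))
  invisible(x)
}
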