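#' Read a Bismark-style CX cytosine report
#'
#' Parses the seven-column dialect (no header): chromosome, 1-based position,
#' strand, methylated count, unmethylated count, context (CG/CHG/CHH),
#' trinucleotide. Zero-depth sites are retained and flagged; malformed rows
#' raise an error naming the offending line.
#'
#' @param path file path.
#' @return a data.frame with columns chrom, pos, strand, count_methylated,
#'   count_unmethylated, context, trinucleotide, depth, zero_depth.
#' @export
read_cytosine_report <- function(path) {
  cols <- c("chrom", "pos", "strand", "count_methylated", "count_unmethylated",
            "context", "trinucleotide")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count_methylated = integer(0),
                      count_unmethylated = integer(0), context = character(0),
                      trinucleotide = character(0))
    out$depth <- integer(0); out$zero_depth <- logical(0)
    return(out)
  }
  d <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                  colClasses = c("character", "character", "character",
                                 "character", "character", "character",
                                 "character"),
                  quote = "", comment.char = "")
  bad_line <- function(test, what) {
    i <- which(test)
    if (length(i))
      stop(sprintf("malformed cytosine report %s: %s at line %d", path, what, i[1]),
           call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(d$pos))
  m <- suppressWarnings(as.numeric(d$count_methylated))
  u <- suppressWarnings(as.numeric(d$count_unmethylated))
  bad_line(is.na(pos) | pos != round(pos) | pos < 1, "non-integer or < 1 position")
  bad_line(is.na(m) | m != round(m) | m < 0, "negative or non-integer methylated count")
  bad_line(is.na(u) | u != round(u) | u < 0, "negative or non-integer unmethylated count")
  bad_line(!d$context %in% c("CG", "CHG", "CHH"), "bad context token")
  bad_line(!d$strand %in% c("+", "-"), "bad strand")
  out <- data.frame(chrom = d$chrom, pos = as.integer(pos), strand = d$strand,
                    count_methylated = as.integer(m),
                    count_unmethylated = as.integer(u),
                    context = d$context, trinucleotide = d$trinucleotide)
  out$depth <- out$count_methylated + out$count_unmethylated
  out$zero_depth <- out$depth == 0L
  out
}

#' Write a cytosine report in the CX dialect
#'
#' @param report data.frame with the seven CX columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path) {
  write.table(report[, c("chrom", "pos", "strand", "count_methylated",
                         "count_unmethylated", "context", "trinucleotide")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read/write a gene-level count matrix (gene_id + one integer column per sample)
#' @param path file path.
#' @return integer matrix with gene ids as row names.
#' @export
read_counts <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts integer matrix genes x samples.
#' @export
write_counts <- function(counts, path) {
  write.table(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#' @param path file path.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "size"))
  setNames(as.integer(d$size), d$chrom)
}

#' Export site calls as bedGraph (0-based half-open, methylation fraction)
#'
#' @param calls a `site_calls` data.frame (see [call_true_methylated()]).
#' @param path output path.
#' @param called_only write only sites called true-methylated.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(calls, path, called_only = FALSE) {
  d <- calls[!is.na(calls$meth_fraction), ]
  if (called_only) d <- d[d$is_true_methylated, ]
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos),
                               score = d$meth_fraction)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
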