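#' Simulate a negative-binomial expression count matrix with planted DEGs
#'
#' Counts for gene g in sample j are drawn from
#' NB(mean = mean_expr * sf_j * 2^(log2fc * I(group_j is the pair's second
#' group)), dispersion = nb_dispersion), with per-sample size factors drawn
#' uniformly in [0.7, 1.4]. Planted differentially expressed genes cycle over
#' the configured group pairs with alternating sign.
#'
#' @param config a [sim_config()] object.
#' @param catalog a `feature_catalog` with at least one gene.
#' @param out_dir optional directory; writes `counts.tsv` (gene_id + one
#'   integer column per sample) and `truth_degs.tsv`.
#' @return a list of class `expr_sim`: `counts` (integer matrix genes x
#'   samples), `samples` (sample, group), `size_factors`, and `truth`
#'   (gene_id, group_a, group_b, true_log2fc = log2 mean_a - log2 mean_b).
#' @export
simulate_expression <- function(config, catalog, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "feature_catalog"))
  if (length(catalog$genes) < 1L) stop("catalog has no genes")
  if (config$n_degs > length(catalog$genes))
    stop("n_degs exceeds the number of genes in the catalog")
  set.seed(stage_seed(config$seed, "expression"))
  gene_ids <- catalog$genes$gene_id
  groups <- rep(config$group_names, each = config$n_per_group)
  sample_ids <- paste0(groups, "_", rep(seq_len(config$n_per_group), config$n_groups))
  sf <- runif(length(sample_ids), 0.7, 1.4)

  lfc <- matrix(0, nrow = length(gene_ids), ncol = config$n_groups,
                dimnames = list(gene_ids, config$group_names))
  truth <- data.frame()
  if (config$n_degs > 0L) {
    deg_idx <- sample(seq_along(gene_ids), config$n_degs)
    n_pairs <- length(config$dmr_pairs)
    for (k in seq_along(deg_idx)) {
      pr <- config$dmr_pairs[[(k - 1L) %% n_pairs + 1L]]
      sgn <- if (k %% 2L == 0L) -1 else 1
      # the pair's second group is shifted; true_log2fc is A relative to B
      lfc[deg_idx[k], pr[2]] <- lfc[deg_idx[k], pr[2]] - sgn * config$deg_log2fc
      truth <- rbind(truth, data.frame(
        gene_id = gene_ids[deg_idx[k]], group_a = pr[1], group_b = pr[2],
        true_log2fc = lfc[deg_idx[k], pr[1]] - lfc[deg_idx[k], pr[2]]))
    }
  }

  mu <- config$mean_expr * outer(rep(1, length(gene_ids)), sf) *
    2^lfc[, match(groups, config$group_names), drop = FALSE]
  counts <- matrix(rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu),
                   nrow = length(gene_ids),
                   dimnames = list(gene_ids, sample_ids))
  sim <- structure(list(counts = counts,
                        samples = data.frame(sample = sample_ids, group = groups),
                        size_factors = setNames(sf, sample_ids), truth = truth,
                        config = config),
                   class = "expr_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write.table(sim$samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth_degs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  sim
}

#' @export
print.expr_sim <- function(x, ...) {
  cat("Simulated expression:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", nrow(x$truth), "planted DEG effects\n")
  invisible(x)
}
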