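#' @importFrom stats pbinom pnorm p.adjust rbeta rbinom rnbinom rnorm runif
#'   lm coef cor.test shapiro.test t.test aov kruskal.test lowess approx
#'   quantile median setNames complete.cases pchisq rlnorm
#' @importFrom utils read.table write.table combn head tail
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# window sums over a sorted numeric position vector: for each position, the sum
# of x over all entries within +/- half of it (inclusive).
window_sum <- function(pos, x, half) {
  stopifnot(!is.unsorted(pos))
  cs <- c(0, cumsum(as.numeric(x)))
  lo <- findInterval(pos - half - 0.5, pos) + 1L
  hi <- findInterval(pos + half + 0.5, pos)
  cs[hi + 1L] - cs[lo]
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample() that never treats a length-1 vector as 1:x
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# deterministic sub-seed for a named stage, kept well below .Machine$integer.max
stage_seed <- function(seed, stage) {
  offs <- c(annotation = 11L, methylome = 29L, expression = 47L,
            dmr = 83L, sites = 131L, pipeline = 197L)
  o <- offs[[stage]] %||% 331L
  (as.integer(seed) %% 1000000L) * 1000L + o
}
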