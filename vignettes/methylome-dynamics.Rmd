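---
title: "Models and methods: methylome-transcriptome dynamics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: methylome-transcriptome dynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

# The problem this package addresses

Reduced representation bisulfite sequencing (RRBS) of a tissue sampled at
several developmental stages — the motivating case is the fetal placenta
(chorioallantois) at three gestational ages, three biological replicates each —
yields per-cytosine counts of methylated and unmethylated reads. Two questions
follow: where does methylation change between stages (differentially
methylated regions, DMRs), and do those changes track gene expression in the
canonical repressive direction (methylation up, expression down)?

`methdyn` implements the full desk-scale chain: calling *true methylated
sites* per sample, annotating sites and regions to genomic features, detecting
DMRs with a smoothed beta-binomial Wald test under empirical-Bayes dispersion
shrinkage, calling differentially expressed genes (DEGs) from a count matrix
with a simplified negative-binomial Wald test, and classifying
methylation-expression concordance for genes that carry both signals. A
deterministic simulator generates every input format the pipeline consumes,
with planted effects, so each stage is validated against known truth.

# Site calling

At a site with $m$ methylated and $u$ unmethylated reads, complete bisulfite
conversion of an unmethylated cytosine would produce methylated calls only by
chance. The test is the exact one-tailed binomial tail
$p = P(X \ge m \mid n = m+u,\ p_0 = 0.5)$, i.e. excess methylation against
$H_0{:}$ methylated $=$ unmethylated $= 0.5$ — the only direction consistent
with calling *methylated* sites. A site is called true-methylated when its
depth is at least 5 and its Benjamini–Hochberg $q$-value is at most 0.01.

Choices worth knowing:

* **Correction scope.** BH runs within each sample, over all tested sites with
  contexts pooled; `call_true_methylated()` records this in its attributes. A
  pooled-across-samples correction is not offered as a separate mode — calling
  is a per-sample operation throughout.
* **The null $p_0 = 0.5$** is deliberately crude (it ignores the conversion
  failure rate); a `p0` argument accepts a conversion-based null such as
  `1 - conversion_rate/100` for users who prefer it.
* Zero-depth sites are parsed and retained (flagged `zero_depth`) but never
  tested and never appear in summaries.

The spike-in control chromosome (`"lambda"`) carries only unmethylated
cytosines; `conversion_rate()` is $100\,\Sigma u / \Sigma(m+u)$ over its
sites. It is excluded from every genomic summary.

# Annotation

Interval conventions, fixed across the package:

* Coordinates are 1-based inclusive (the `GenomicRanges` convention); BED
  import/export converts to and from 0-based half-open losslessly via
  `rtracklayer`.
* **Promoter** := 1000 bp upstream of the TSS through the TSS, strand-aware.
* **CGI shores** := 2000 bp flanking each CpG island, clipped at neighbouring
  islands and chromosome ends.
* **Gene association** uses the 1 kb rule: a query belongs to every gene whose
  span extended by 1 kb on both ends intersects it. The boundary is sharp:
  999 bp upstream associates, 1001 bp does not.
* **Feature assignment is multi-label.** A region spanning an exon–intron
  junction counts under both labels; a single-label priority mode
  (promoter > utr5 > exon > utr3 > intron > repeat > shore > cgi) exists
  behind the `priority` flag for summaries that need disjoint categories.
* Feature-level methylation percentages are **unweighted means of per-site
  fractions** over tested sites (depth ≥ 5); whether to weight by coverage is
  a genuine open choice and the unweighted decision is recorded in the
  profile's attributes. A feature with no tested site reports `NA`, never 0.

`group_stats()` provides the descriptive battery for stage comparisons:
Shapiro–Wilk normality per feature, pairwise Welch $t$ between stages, one-way
ANOVA across features, and Kruskal–Wallis with Dunn's post-hoc pairwise $z$
(tie-corrected, Bonferroni-adjusted). Dunn's statistic is implemented in the
package because no dedicated post-hoc package is declared as a dependency; it
is validated against a hand computation in the test suite.

# DMR detection

## Model

Methylated counts at site $j$, sample $i$, follow a beta-binomial with mean
$\mu_j$ (group-specific) and dispersion $\varphi_j$, parameterised so the
variance of a count at depth $n$ is $n\mu(1-\mu)\bigl(1+(n-1)\varphi\bigr)$;
$\varphi = 0$ degenerates to the binomial. Sites enter testing when covered
(depth ≥ 1) in every sample of both groups; the per-sample "true methylated"
calls are *not* a prerequisite — they serve descriptive summaries. CG, CHG and
CHH form separate streams that never mix within a region.

## Dispersion shrinkage

Per site, a method-of-moments estimate pools the within-group scatter of
replicate proportions. With three replicates per group these estimates are
extremely noisy and frequently non-positive, so they are shrunk toward the
genome-wide mean dispersion with weight proportional to the site's total
depth; non-positive or inestimable sites take the prior exactly. The blend is
on the **natural scale**: a geometric (log-scale) blend is systematically
biased low, and an underestimated $\varphi$ makes every downstream Wald test
anticonservative — in null simulations the log-scale variant inflated the
$p<0.05$ rate beyond 0.10 while the natural-scale blend sits near 0.05–0.08.
Estimates are clipped to $[10^{-6}, 0.999]$.

## The windowed Wald statistic

Raw per-site power at a 30% methylation difference with depth ~30 and three
replicates per group is nowhere near the region-calling threshold
($p < 10^{-5}$), so evidence is pooled over a 500 bp moving window, as
smoothing-based DMR callers do. Two design points matter:

1. **Common weights across groups.** The statistic is the inverse-variance
   weighted window average of *per-site group differences*
   $d_j = \hat p_{1j} - \hat p_{2j}$, not a difference of group-specific
   coverage-weighted window means. With heterogeneous methylation inside a
   window (an island boundary, say), group-specific weights let each group's
   random depths re-weight the mixture differently, adding between-group
   variance the beta-binomial model does not account for; in calibration runs
   this inflated the $10^{-5}$ tail roughly seven-fold even with the true
   dispersion plugged in. Common weights cancel the heterogeneity exactly.
2. **Variance matched to the estimator.** Each $d_j$ gets the beta-binomial
   variance of both groups' pooled proportions at that site, using the shrunk
   $\varphi_j$ and a per-site mean with a Laplace pseudo-count; the windowed
   statistic's variance is the inverse of the summed weights. Reported
   smoothed group means ($\hat\mu_1$, $\hat\mu_2$) remain the familiar
   coverage-weighted window averages.

Two-sided $p$-values come from the standard normal. Null simulations at the
package defaults give a $p<0.05$ fraction of 0.04–0.06 and zero sites below
$10^{-5}$ among $3\times10^5$ tested sites.

## Region calling and boundary refinement

Significant sites ($p <$ `p_threshold`, default $10^{-5}$) with a consistent
difference sign and gaps ≤ `merge_gap` (100 bp) form maximal runs; a run is a
DMR when it spans ≥ `min_len` (50 bp), contains ≥ `min_sites` (3) tested
sites, and ≥ `pct_sig` (50%) of its member sites are significant. Because the
windowed statistic lends power to neighbours, significance spreads up to half
a window (~160 bp in practice) beyond a true region's edges. Candidate
regions are therefore **trimmed**: a ±60 bp coverage-weighted local average of
the *unsmoothed* difference is compared against the run's peak local
difference, and boundary sites below `refine_frac` (0.5) of the peak (or of
the opposite sign) are dropped from both ends. At threshold one-half, the
crossing point of a step-shaped region's convolved profile sits at the true
edge, so the trim is unbiased there; anchoring the peak at the strongest
local difference (not the argmax of the Wald statistic, which plateaus under
smoothing) keeps the anchor inside the region. All reported DMR methylation
summaries use raw pooled counts, never smoothed values, and
`dmr_methylation_log2fc()` is $\log_2\frac{\bar\mu_1+0.01}{\bar\mu_2+0.01}$.

In planted-truth benchmarks (50 regions of 50–500 bp, a 0.30 methylation
difference, depth 30, 3 vs 3) the caller recovers ~95% of planted regions
with ~100% precision; single planted 200 bp regions are localised with
Jaccard ≥ 0.8 in 18 of 20 seeds. Regions shorter than ~100 bp at default CpG
density are the main misses — they carry too few covered CpGs to clear
`min_sites` and the smoothing dilutes them most.

# Differential expression

The DE stage is a deliberately simplified negative-binomial Wald pipeline —
no covariates, no fold-change shrinkage, no independent filtering — because
its role is to feed the integration stage under the decision rule
*Bonferroni-adjusted $p < 0.05$ and $|\log_2 FC| > 1$*:

* **Normalisation**: median-of-ratios size factors, rescaled to geometric
  mean 1.
* **Dispersion**: per-gene method of moments on normalised counts (pooled
  within-group variance), shrunk on the natural scale toward a lowess trend
  of dispersion on mean (`prior_df = 4`); genes with literally zero replicate
  variance take the lower clip ($10^{-8}$).
* **Test**: $\log_2 FC = \log_2\frac{\bar q_A + 0.5}{\bar q_B + 0.5}$ with a
  configurable 0.5 pseudo-count; the standard error is the delta-method
  NB variance of each group mean; two-sided normal $p$; all-zero genes are
  excluded from testing and from the Bonferroni denominator.

## Power at the study scale

A power analysis worth stating explicitly: with dispersion $\alpha = 0.1$ and
three replicates, a $|\log_2 FC| = 1.5$ effect at mean 200 has Wald
noncentrality $\approx 3.9$. Bonferroni over 1000 genes demands $|z| > 4.06$,
capping sensitivity near 0.42 for *any* calibrated NB Wald test — no honest
implementation reaches 0.6 there. The packaged sensitivity benchmark
therefore runs at the simulator's own scale (30-gene catalogs, 10 planted
effects, aggregated over ten seeds), where the Bonferroni threshold is
proportionally milder and measured sensitivity is ~0.65–0.75. Null
calibration is checked separately at 1000 genes, where the raw $p<0.05$
fraction stays within [0.02, 0.10].

# Integration

For one comparison, `overlap_deg_dmr()` joins flagged DEGs with DMR-carrying
genes (1 kb association rule) and emits one record per (gene × DMR × region
label), with region labels in the vocabulary Promoter, Utr5, Utr3, Exon,
Intron, TSS, TES (TSS/TES = overlap of the start/termination site ± 1 kb).
Agreement is classified from the two fold-change signs alone:

* `concordant` — strictly opposite signs (the canonical repressive pattern);
* `discordant_positive` — both strictly positive, the published tables'
  "No *" pattern of positive gene-body methylation–expression correlation;
* `discordant_other` — everything else, including both-negative pairs and
  exact zeros.

Both-negative pairs are *not* classified as positive correlation: the
reference overlap table shipped with the package prints plain "No" for every
such row, and the package follows that evidence. The two promoter rows of the
reference table whose printed call departs from the sign rule (the footnote
concerns gene-body methylation only) are flagged in the fixture and excluded
from the row-level golden test. Gene uniqueness keys on the stable gene id,
falling back to the gene name only where an id is missing.

# The simulator: what it emulates, and what it does not

`sim_config()` defaults describe a three-stage, three-replicate RRBS +
RNA-seq study:

| parameter | default | rationale |
|---|---|---|
| `cpg_rate` | 100 CpG/kb | RRBS enriches CpG-dense MspI fragments; CGI-like density |
| `coverage_mean`, `coverage_dispersion` | 30, 8 | typical RRBS per-site depth; negative-binomial spread |
| `baseline_meth_by_feature` | bimodal (CGI 0.20, promoter 0.15, UTR5 0.10, shore 0.45 vs gene body/repeat 0.80–0.90) | mammalian CpG methylation is bimodal; lowest at 5' UTRs, then promoters and CGIs |
| `site_dispersion` | 0.02 | across-replicate beta-binomial overdispersion of a homogeneous tissue |
| `n_dmrs`, `dmr_delta`, `dmr_len_range` | 9, 0.30, 50–500 bp | the ~30% methylation-difference scale and sub-kilobase lengths typical of reported DMRs |
| `frac_chh_chg` | 0.02 | non-CG cytosines a small minority, nearly unmethylated, so called mCs are >97% CG |
| `conversion_failure` | 0.0059 | a 99.41% conversion rate on the unmethylated lambda spike-in |
| `control_chrom_length`, `control_site_rate` | 200 kb, 0.25/bp/strand | an oversampled control so conversion estimates carry ~10^5 cytosines |
| `deg_log2fc`, `nb_dispersion`, `mean_expr` | 1.5, 0.1, 200 | planted expression effects above the decision threshold at moderate counts |

Planted DMRs shift the designated pair's second group by ±`dmr_delta`,
flipping the shift direction when it would saturate at 0 or 1 so the realised
difference keeps its full magnitude; the truth table records the *realised*
per-region mean difference. A configurable fraction of DMRs is shared by two
group pairs, emulating genes recurrently affected across comparisons.
CpG sites are emitted symmetrically on both strands (the CX-report default)
and tested as separate sites.

Features of real data the simulator does **not** reproduce — and which
passing tests therefore say nothing about: spatial autocorrelation of
methylation beyond the planted block structure (each site draws its
beta-binomial level independently), coverage biases of library preparation,
read-level errors and PCR duplicates, allele-specific (parent-of-origin)
methylation, and annotation error in real genomes. The calibration results
hold under the simulator's independence assumptions; on real data with local
correlation the windowed test will be somewhat anticonservative, which is the
usual property of smoothing-based callers.

# Determinism and numerical choices

* All randomness flows from a single integer seed; each simulator stage draws
  from a named substream (`seed*1000 + stage offset`), so identical seeds
  give bit-identical files (hash-checked in the tests).
* Floors and clips: dispersion $[10^{-6}, 0.999]$ (beta-binomial) and
  $[10^{-8}, 10]$ (NB); $\mu(1-\mu)$ floored at $10^{-3}$ in Wald variances;
  0.5 pseudo-count in expression fold changes, 0.01 pseudo-fraction in
  methylation fold changes, Laplace (+1/+2) pseudo-counts in per-site
  variance means.
* Ties and degenerate inputs: empty inputs return typed empty results rather
  than errors wherever a downstream stage can proceed; zero-depth groups are
  skipped and recorded; a region's direction label ties toward the first
  group at exact equality (a zero-measure event).
* Problem sizes in the packaged checks: the test suite uses one 80 kb
  chromosome (≈16k CpG rows) for module fixtures, a 4 × 400 kb genome
  (≈3.2 × 10^5 tested sites) for recovery and null-rate benchmarks, and
  10^3–10^4-unit simulations for the statistical calibrations — sizes chosen
  so the whole suite reruns in a few minutes on one core while keeping
  Monte-Carlo error well below every asserted margin.

# Known limitations

* DMR detection needs ≥ 2 replicates per group for dispersion information and
  loses sub-100 bp regions at default CpG density.
* The per-sample FDR correction pools contexts; a context-stratified
  correction would change marginal q-values for non-CG sites.
* The DE stage is not a replacement for a full GLM framework: no covariates,
  no shrunken fold changes, and Bonferroni (as the decision rule demands)
  rather than FDR.
* `run_pipeline()` always recomputes every stage; there is no incremental
  re-execution. Determinism makes a full rerun cheap at desk scale.
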