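Package: methdyn
Title: Methylome-Transcriptome Dynamics from Bisulfite Cytosine Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for studying DNA methylation dynamics and
    their relationship to gene expression across developmental stages, built
    around reduced representation bisulfite sequencing (RRBS). Starting from
    Bismark-style per-cytosine reports it calls true methylated sites with a
    one-tailed binomial test under FDR control, annotates sites and regions to
    genomic features (CpG islands, shores, promoters, UTRs, exons, introns,
    repeats), detects differentially methylated regions with a smoothed
    beta-binomial Wald test using empirical-Bayes dispersion shrinkage, calls
    differentially expressed genes from count matrices with a simplified
    negative-binomial Wald test, and classifies methylation-expression
    concordance for genes carrying both signals. A deterministic simulator
    generates toy genome annotations, multi-group cytosine reports with
    planted differentially methylated regions and a lambda spike-in
    conversion-control chromosome, and negative-binomial expression counts
    with planted effects, so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
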