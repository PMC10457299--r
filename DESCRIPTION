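Package: bulkscan
Title: QTL-Seq Bulked-Segregant Analysis with Simulated RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulked-segregant QTL mapping (QTL-seq) from pooled whole-genome
    sequencing of phenotypic extreme bulks drawn from a recombinant inbred
    line (RIL) population. Provides hard filtering of variant sites on
    caller quality annotations, the three bulk-genotyping criteria used for
    biparental pools, per-site SNP-index and delta(SNP-index) statistics,
    sliding-window genome scans with two-stage binomial simulation of null
    confidence bands, candidate-region calling and summarization, variant
    effect annotation against gene models, segregation goodness-of-fit and
    interval utilities, and a forward simulator of RIL populations, traits,
    extreme bulks and pooled read counts that emits analysis-ready VCF.
License: MIT
Encoding: UTF-8
Imports:
    vcfR,
    Rcpp,
    rtracklayer,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
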