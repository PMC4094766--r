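Package: triome
Title: Integrative Staged Expression Analysis of lncRNA, miRNA and mRNA Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for integrating probe-level lncRNA, miRNA
    and mRNA microarray intensities measured across five stages of esophageal
    carcinogenesis (one pooled sample per stage). Implements median
    normalization with an intensity floor, detection and co-expression calling,
    two-fold differential-expression set algebra against the normal stage
    (per-stage, union and intersection sets), directional stage-pattern
    selection, intersection of predicted miRNA targets with downregulated
    mRNAs, cis-neighbor functional assignment of lncRNAs from genomic
    coordinates, local hypergeometric/EASE GO-term enrichment with
    Benjamini-Hochberg correction, and construction of the tripartite
    miRNA-mRNA-lncRNA network linked through shared enriched GO terms. A
    synthetic-data generator with planted truth provides fully testable inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    ape,
    rtracklayer,
    GenomicRanges,
    IRanges,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
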