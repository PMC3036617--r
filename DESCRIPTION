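Package: zdimorph
Title: Sex-Biased Gene Expression Analysis for Avian Z-Chromosome Dosage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting sex-biased gene expression on
    songbird expression microarrays and relating it to Z-chromosome dosage.
    Covers probe-level quantile normalization and median-polish summarization,
    standard-deviation and cross-species (CGH) probe-mask filtering with exact
    accounting, a from-scratch two-class unpaired Significance Analysis of
    Microarrays (SAM) permutation test with FDR-targeted delta selection,
    collapse of redundant probe sets (ESTs) to non-redundant genes with
    ambiguity detection, Fisher exact tests of Z-chromosome enrichment against
    the array background, and cross-species concordance of sex-biased gene
    sets. Includes a probe-level data simulator with known ground truth that
    emulates incomplete Z dosage compensation, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
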