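Package: cnupd
Title: Allele-Specific Copy Number, LOH and Uniparental Disomy Analysis for
    SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for the genomic characterization of
    near-pure tumor samples (e.g. cancer cell lines) from allele-specific
    SNP-array data. Computes LogR ratios against a reference intensity pool,
    calls genotypes from B-allele frequencies, segments LogR profiles by
    recursive binary segmentation with permutation-based split acceptance,
    assigns categorical copy-number calls (-1/0/+1/+2), detects probe-level
    LOH and homozygous deletions, finds and classifies copy-neutral LOH
    (uniparental disomy) events into six categories, discovers recurrently
    altered minimal common regions by a segment-relocation permutation test
    with FDR control, scores per-sample genomic instability with tertile
    grouping and association tests, integrates copy number with expression,
    and assigns molecular subtypes by nearest-centroid Pearson correlation.
    Ships a synthetic allele-specific array generator with planted truth and
    a curated mutation/copy-status table for a bladder-cancer cell line
    panel.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    yaml,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
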