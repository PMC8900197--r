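Package: nicscreen
Title: Non-Invasive Chromosome Screening from Shallow Sequencing Bin Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copy-number analysis for non-invasive pre-implantation genetic
    testing of aneuploidies (niPGT-A) from low-pass whole-genome sequencing of
    embryo liquid-biopsy samples (spent culture medium, blastocoel fluid) and
    biopsy references. Provides a read-count simulator for 1 Mb genome bins
    with GC bias, amplification overdispersion, dropout, mosaicism and
    maternal contamination; GC and reference-panel normalization of bin
    counts into copy-ratio profiles; circular binary segmentation with
    permutation p-values; per-chromosome copy-number, mosaicism and sex
    calling with karyotype strings; and diagnostic scoring (sensitivity,
    specificity, predictive values, ploidy and sex concordance, chi-square
    comparisons) of calls against a gold-standard reference, including
    bundled summary counts from a published 148-embryo SCM/BF validation
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
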