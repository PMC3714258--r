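Package: seqpcr
Title: Multi-Parallel qRT-PCR Transcriptome Profiling of Somatic Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-parallel qRT-PCR expression profiling of
    time-course experiments contrasting embryogenic and non-embryogenic plant
    cultures. Implements delta-delta-Ct relative quantification against a
    median-of-wells reference gene, detection calling under a 40-cycle ceiling,
    statistically gated 2- and 10-fold modulation calls (per-gene ANOVA with
    Benjamini-Hochberg correction plus pairwise t-tests), temporal-trajectory and
    genotype-contrast (SE-specific) classification, k-means expression pattern
    clustering, PCA quality control, annotation tallies, exact small-sample
    nonparametric phenotype tests, and a synthetic Ct-data generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
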