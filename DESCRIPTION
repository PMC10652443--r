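Package: panelprofiler
Title: Targeted-Panel Tumor Profiling: Binomial SNV Calling, MSI Scoring,
    Mutational Burden and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a targeted-panel tumor profiling pipeline for small
    bowel cancer cohorts: somatic single-nucleotide variant detection by an
    exact binomial test on pileup counts with the standard filter cascade
    (allele fraction, supporting reads, strand bias, base quality,
    population frequency, functional class), a binomial tail-probability
    model for per-locus microsatellite instability with MSI scoring and
    MSI-H/MSS classification, tumor mutational burden per megabase with
    driver exclusion, and cohort-level statistics comparing mutation
    frequencies and immunotherapy biomarkers (MSI-H proportion, TMB, PD-L1
    TPS) across anatomic sites and cohorts. A synthetic-cohort generator
    emulates the assumed data structure so that every stage runs and is
    tested without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
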