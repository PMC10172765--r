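Package: subtelo
Title: Multi-Scale Subtelomeric Read-Density and TERRA Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies chromatin accessibility and transcription near
    chromosome ends from aligned sequencing reads. Builds nested
    end-anchored subtelomeric windows (5, 45, 450 and 4,500 kb by default)
    on an effective chromosome end derived from a telomere annotation,
    converts window read counts to per-bp densities normalized by each
    chromosome's genome-average density, and compares genotypes through
    per-chromosome fold changes with Tukey multiple-comparison statistics.
    Also implements reference-gene-normalized relative qPCR expression
    (delta-delta-Ct), aggregation of per-chromosome-end cytological signal
    measurements (per-cell counts, intensity per cell area, damaged versus
    non-damaged ratios) with the associated nonparametric tests, and a
    synthetic-data generator that plants known subtelomeric enrichment so
    every stage of the pipeline is verifiable against closed-form
    expectations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
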