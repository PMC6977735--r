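Package: medmir
Title: Paired Tumor Methylation and MicroRNA Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired primary and recurrent tumor
    samples profiled by methylation-dependent restriction enzyme
    sequencing (MeD-seq) and TaqMan Low Density Array (TLDA) microRNA
    cards. Implements positional read filtering on the LpnPI recognition
    motif, per-site read count tracks, region read-count aggregation over
    TSS, CpG-island and gene-body annotations, chi-square calling of
    differentially methylated regions with sliding-window binning of
    significant sites, median-Ct normalization and paired differential
    expression of microRNAs with batch adjustment and FDR control,
    hierarchical clustering with a pair-cohesion statistic, and cohort
    descriptive statistics. A synthetic-data module generates reference
    genomes, methylomes with planted DMRs, MeD-seq reads, batched Ct
    matrices and clinical tables with truth records so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite
Config/testthat/edition: 3
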