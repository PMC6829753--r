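Package: methylscape
Title: Methylome Segmentation, PMD Detection and DMR Classification for
    Whole-Genome Bisulfite Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for base-resolution comparison of DNA methylomes from
    whole-genome bisulfite sequencing (WGBS), built around the contrast of
    iPSC-derived versus native retinal pigment epithelium: change-point
    segmentation of methylomes into domains and detection of partially
    methylated domains (PMDs), Methylated Domain Landscape plots, feature-level
    clustering of samples using raw methylation, PCA or independent component
    analysis, calling and etiological classification of differentially
    methylated regions, classifiers for imprinted-DMR status and X-chromosome
    inactivation escape, and non-CpG (CHG/CHH) methylation context profiling.
    Includes a synthetic WGBS cohort generator that plants all the structure
    the downstream analyses assume, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
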