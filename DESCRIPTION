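Package: adacomplex
Title: ChIP-Seq Peak Classification, Spectral-Count Quantification and
    Hydrodynamic Sizing of SAGA-Module Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising chromatin-bound and soluble forms of
    SAGA-related acetyltransferase complexes. Builds reproducibility-filtered
    reference peak sets from multi-factor, multi-replicate ChIP-seq peak calls
    and classifies each locus as canonical SAGA binding, Ada2b-only (ADA
    complex) binding, or other; computes RPM coverage, log2 ChIP/input
    enrichment, population z-scores, nearest-TSS assignment, gene-biotype
    fractions and TSS-centred intensity matrices; quantifies MudPIT
    shotgun-proteomics runs by the distributed normalized spectral abundance
    factor (dNSAF) with shared-peptide distribution and enrichment
    thresholding; and estimates native molecular mass from gel-filtration
    Stokes radii and sedimentation coefficients via the Svedberg equation.
    A seeded synthetic-data module generates every input format the pipeline
    consumes, with planted ground truth, so the full analysis is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
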