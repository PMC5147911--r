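Package: mitomix
Title: Simulation and Deconvolution of Mitochondrial Sequencing Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying two-person mitochondrial DNA mixtures
    sequenced on a deep low-error short-read platform and a high-error
    long-read platform. Provides a dual-platform read simulator over a
    circular reference tiled by two overlapping long-PCR amplicons
    (with homopolymer-associated deletion errors for the long-read
    chemistry), a variant-allele-frequency thresholding SNP caller with
    left-alignment normalisation, recall/precision/F1 concordance grids
    over VAF threshold pairs, phasing of amplicon-spanning long reads
    into contributor pools, private-variant deconvolution of short read
    pairs, and reference-guided per-contributor consensus reconstruction
    with Nx/NGAx assembly statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    Rsamtools,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
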