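Package: hicemt
Title: 3D Genome Organization Analysis Across the EMT Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for analysing three-dimensional genome
    organization along the epithelial-mesenchymal transition (EMT) spectrum.
    Provides sparse binned Hi-C contact-matrix handling with iterative-correction
    balancing and observed/expected transforms; A/B compartment calling from the
    leading eigenvector of the O/E correlation matrix, compartment switch
    classification between cell states, and expression concordance; insulation
    score TAD calling with a Stable/Expand/Shrink/Shift boundary-change taxonomy
    and epithelial/mesenchymal TAD assignment; EMT signature refinement and
    scoring with histone-signal correlation; aggregate contact analysis at TADs
    and locus pairs with 3C-qPCR normalization; single-cell Hi-C structure
    embedding by distance geometry with mirror-aware r.m.s.d clustering; and a
    fully seeded synthetic-data generator that plants every structure the
    pipeline is designed to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
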