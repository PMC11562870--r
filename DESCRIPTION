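Package: epitrichome
Title: Multi-Tissue Histone-Mark Integration for Plant Trichome Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for integrating multi-tissue histone-mark
    ChIP-seq peak calls with transcriptome data in plants, modelled on
    glandular-trichome epigenome studies. Consolidates replicate peak calls
    into high-confidence sets (a Gaussian copula mixture model of the
    irreproducible discovery rate for narrow and mixed peak types,
    reciprocal-overlap intersection for broad domains), performs exact
    genomic interval algebra, co-localization and bivalency statistics,
    tissue-specific differential chromatin and expression analysis,
    hypergeometric over-representation and preranked gene-set enrichment,
    position-weight-matrix motif enrichment in tissue-specific acetylated
    loci, and distal enhancer to target-gene prediction. Ships a seeded
    synthetic-study generator with a ground-truth manifest so every stage
    can be validated end-to-end on planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
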