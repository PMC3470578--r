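Package: episegsom
Title: Combinatorial Genome Segmentation and Self-Organizing Maps for
    Histone Modification Patterns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotation-independent exploration of multi-sample ChIP-seq
    histone modification data. Per-position read counts are discretized
    into binary modification states via an enrichment ratio against a
    whole-cell-extract control; the genome is then partitioned
    combinatorially using either all marks of one reference cell type
    (ES-segmentation) or one reference mark across all cell types
    (EV-segmentation). Each retained segment carries a binary
    combinatorial epigenetic profile (CEP) plus fractional coverages by
    the remaining modification states, forming an epigenetic profile (EP)
    that is clustered on a deterministic Kohonen self-organizing map with
    linear PCA initialization. The package renders the resulting mosaic
    SOM-images together with supporting maps (population, CEP islands,
    coverage atlas, segment length, CpG density, expression present-call,
    gene-set fraction, and hypergeometric chromosomal enrichment), and
    ships a seeded synthetic-data generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
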