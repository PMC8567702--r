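Package: KaryoTracer
Title: Collinearity, Ks-Based WGD Dating, Ancestral Karyotype
    Reconstruction and PAV Calling for Plant Comparative Genomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects collinear (syntenic) gene blocks between annotated
    genomes by anchor chaining, estimates synonymous substitution rates
    (Ks) per collinear gene pair with the Nei-Gojobori counting method,
    characterises Ks distributions by kernel density estimation and
    Gaussian multipeak fitting, corrects for lineage-specific rate
    variation and dates whole-genome duplications against the
    monocot-eudicot calibration. Reconstructs ancestral proto-chromosomes
    by cross-genome painting under a telomere-centric repatterning model,
    classifies chromosome rearrangement events (end-to-end joining, nested
    fusion, arm exchange) between evolutionary nodes, and calls
    presence/absence variation between closely related genomes. Ships a
    multi-lineage genome-evolution simulator with full ground-truth logs,
    including a packaged trajectory modelled on the descent of the extant
    coconut karyotype from ten monocot proto-chromosomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
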