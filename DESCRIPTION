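Package: karnerpop
Title: Population Genomics of the Karner Blue Butterfly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for range-wide conservation population genomics of the
    Karner blue butterfly (Plebejus samuelis) and its close relatives:
    contamination-aware cleanup of degraded short-read alignments, depth-based
    genomic masking, locus selection and export to STRUCTURE, BA3-SNPs and
    EIGENSTRAT formats, Reich's small-sample F_ST estimator with Mantel
    isolation-by-distance testing, cross-species windowed diversity comparison
    with matched-pair tests, between-group protein divergence, and a screen
    for fixed, potentially deleterious single-amino-acid variants with
    solvent-accessibility classification. Includes seeded synthetic-data
    generators that reproduce the statistical structure each stage assumes so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    geosphere,
    IRanges,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
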