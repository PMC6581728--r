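Package: splicevol
Title: Comparative Evolution of Alternative Splicing from Junction Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies alternative splicing (AS) events
    (intron retention, alternative donor/acceptor, exon skipping) from
    splice-junction evidence tables, computes percent-spliced-in (PSI),
    identifies conserved exon-exon junctions between species by
    reciprocal-best translated alignment, annotates premature termination
    codons under the 50-nt nonsense-mediated-decay rule, extracts
    splice-site determinant features (alternative splice-site distances,
    polypyrimidine and UA tracts, branch sites, k-mer enrichment), trains
    and evaluates splicing-code and AS-conservation classifiers, and builds
    PSI/binary AS profiles with bootstrap hierarchical clustering. Ships a
    seeded multi-species synthetic cohort generator so the whole pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
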