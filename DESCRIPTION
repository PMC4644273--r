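Package: diffpickr
Title: Bait-Guided Differential Read Picking for Genome Recovery from
    Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers a target organism's genome from co-culture shotgun
    sequencing by differential read picking: chimera-rich whole-genome
    amplification (WGA) reads from a pure culture serve as bait to label
    contigs assembled from direct-shotgun reads, reads placed on
    bait-supported contigs are recovered across two sequencing platforms,
    and the picked reads are re-assembled. Ships a truth-labelled
    co-culture read simulator with a WGA chimera and amplification-bias
    model, sliding-window quality trimming, a de Bruijn assembler that
    tracks read placements, genome statistics from GenBank flat files,
    ANIb average nucleotide identity, and CRISPR direct-repeat/spacer
    array detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
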