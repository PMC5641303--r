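Package: RNAtemplate
Title: Template-Based Generation of RNA Secondary Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates the secondary structure of an RNA sequence from the
    experimentally determined structure of a homologous template. Conserved
    base pairs are transferred through a pairwise sequence alignment, the
    transferred structure is decomposed into hairpins and stems, elements with
    too many mapping-inconsistent positions are re-predicted de novo, and the
    reliability of the assembled structure is quantified by a z-score against
    a dinucleotide-shuffle bootstrap null. Includes a built-in deterministic
    folding engine (maximum canonical pairing) and an adapter for the
    ViennaRNA command-line programs, a Zhang-Shasha tree edit distance on
    structure trees, cross-validation utilities, and a synthetic homolog
    generator for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
SystemRequirements: Optional ViennaRNA command-line tools (RNAfold,
    RNAduplex, RNAeval) for the production folding engine.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
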