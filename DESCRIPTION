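Package: repeatscape
Title: Microsatellite and Repeat-Family Landscapes from Genome Survey Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome survey sequences (fosmid-end or
    other random reads): tandem-repeat (microsatellite) detection by
    candidate-period discovery and wraparound dynamic-programming alignment,
    canonical motif classification, per-motif landscape statistics (relative
    abundance and frequency, density, length-class histograms), de novo
    interspersed repeat-family discovery by all-vs-all alignment and
    single-linkage clustering with star-alignment consensus building,
    flow-cytometry genome-size estimation, and survey-level extrapolations
    (library coverage, sampling fraction, gene count and density). Includes
    a seeded synthetic read simulator with planted, ground-truthed repeats
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
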