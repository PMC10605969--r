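Package: panbdg
Title: Implicit Colored Compacted De Bruijn Graphs on the Bidirectional FM-Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a memory-conscious, implicit representation of the colored
    compacted de Bruijn graph (ccdBG) of a pan-genome on top of a bidirectional
    FM-index.  Graph nodes are never stored as explicit sequences; a node
    vector, two marker bit vectors and two rank-to-identifier maps suffice for
    constant-time graph navigation (neighbor jumps by character, predecessor
    jumps through a specific edge, k-mer to node lookup accelerated by
    checkpoint k-mers).  On this foundation the package offers symmetric
    subgraph extraction with DOT/GFA/TSV export, lossless approximate pattern
    matching under edit distance (up to 4 errors) using search schemes, mapping
    of matches to both graph node paths and per-sequence text coordinates, a
    neighbor-variant scan for co-occurring mutations, and a seeded synthetic
    pan-genome and read generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
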