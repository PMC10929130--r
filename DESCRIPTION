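Package: gmem
Title: Maximal Exact Matches Between Sequences and Labeled Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds maximal exact matches (MEMs) of length at least kappa
    between DNA query sequences and labeled sequence graphs. Implements
    string-vs-string MEM enumeration over a bidirectional BWT-style index,
    kappa-MEMs spanning exactly L graph nodes via sentinel-wrapped
    path-concatenation texts with a range-minimum-query filtered cross
    product, and a relaxed scheme for elastic founder graphs (node, edge,
    full-node, edge-prefix and edge-suffix MEMs) with decomposition-based
    stitching of long matches. Includes GFA v1 subset I/O, semi-repeat-free
    validation, unary-path merging, seeded synthetic data generators and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
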