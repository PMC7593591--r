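Package: ssuflash
Title: SSU rRNA Profiling and Targeted-Assembly Support for Shotgun Metagenomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Small-subunit (SSU) rRNA centered analysis of shotgun
    metagenomes: curation of SSU reference databases (LSU-fragment removal,
    k-mer entropy masking, vector screening, greedy identity clustering),
    extraction of SSU rRNA read pairs by seeded alignment at a minimum
    identity cutoff, last-common-ancestor taxonomic profiling on SILVA-style
    taxonomy strings, informational-redundancy quality control, targeted
    assembly parameter rules and SSU region extraction from contigs,
    multi-sample comparison with a normalized abundance-weighted taxonomic
    Unifrac-like distance, and assembly-graph "fishing" to link SSU rRNA
    sequences to genome bins. Seeded synthetic fixture generators emulate
    every input format so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
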