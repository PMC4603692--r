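Package: tommscan
Title: Genome Mining of Thiazole/Oxazole-Modified Microcin Gene Clusters
Version: 0.1.0
Authors@R:
    person("tommscan", "maintainers", email = "tommscan@example.org",
           role = c("aut", "cre"))
Description: Mines annotated bacterial and archaeal genomes for
    thiazole/oxazole-modified microcin (TOMM) biosynthetic gene clusters.
    Extracts 10-kb neighbourhoods around YcaO (D protein) anchor genes,
    detects candidate precursor peptides from annotated short genes and
    six-frame open reading frames by C-terminal Cys/Ser/Thr composition,
    groups neighbourhoods into families by a weighted homology-plus-synteny
    score, classifies families as TOMMs by evidence rules, and builds
    protein sequence similarity networks. Includes a ground-truthed
    synthetic genome generator so the whole pipeline is verifiable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
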