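Package: morphpars
Title: Maximum Parsimony Analysis of Discrete Morphological Character
    Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equal-weights unordered (Fitch) maximum parsimony for discrete
    morphological character matrices with missing data and polymorphic
    cells. Reads and writes a TNT-style matrix dialect and a NEXUS subset;
    searches for all most-parsimonious trees by exhaustive enumeration,
    branch-and-bound, or seeded random-addition heuristic search with
    NNI/SPR/TBR branch swapping; computes strict consensus trees,
    Robinson-Foulds distances, per-character step minima and maxima,
    ensemble consistency and retention indices, zero-minimum-length branch
    collapsing, and unambiguous synapomorphy diagnoses from all
    most-parsimonious reconstructions. Includes an Mk-model simulator for
    validating analyses against known trees, and a bundled 29-taxon,
    56-character capitosaur (Triassic temnospondyl) cranial matrix in two
    coding variants of Yuanansuchus maopingchangensis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
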