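Package: forestclust
Title: Structure-Based Clustering of RNA Families by Tree Edit Distance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads multi-family Stockholm alignments (Rfam seed dialect),
    normalizes WUSS consensus structure annotation to plain dot-bracket
    strings, interprets each structure as an ordered forest (base pairs as
    interior nodes, unpaired bases as leaves), and computes all-vs-all full
    tree edit distances under a nucleotide-count cost model (indel cost 2
    for pair nodes, 1 for unpaired nodes).  The resulting distance matrix
    is clustered agglomeratively (UPGMA, single or complete linkage) into
    dendrograms that can be exported as Newick, rendered as SVG with
    regex-driven leaf highlighting, and scored against externally defined
    family groupings (Rfam clans, RNA classes) with the maximal Jaccard
    index and two dispersion coefficients.  Includes a synthetic Rfam-like
    dataset generator with planted structural classes and clans for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
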