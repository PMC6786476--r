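Package: plastrophy
Title: Structural and Comparative Analysis of Reduced Heterotroph Plastomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize structurally degraded plastid genomes of
    heterotrophic plants. Detects large inverted repeats from self-similarity,
    read coverage and split read-pair evidence; partitions circular plastomes
    into the quadripartite LSC/SSC/IR architecture; classifies genes as intact,
    pseudogenized or absent against an autotrophic reference and verifies
    absences in the read pool; censuses dispersed maximal repeats in four
    orientation classes and perfect tandem repeats; builds locally collinear
    blocks across plastomes and measures rearrangement (breakpoint and signed
    reversal) distances pairwise and over a fixed phylogeny; and tests for
    correlated Brownian-motion evolution of structural traits with likelihood
    ratio tests. A synthetic-data layer generates reference/degraded plastome
    pairs, paired-end reads, trees and traits with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
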