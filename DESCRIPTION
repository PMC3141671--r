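Package: dupetime
Title: Timing Gene Duplications Relative to the Cyclostome-Gnathostome Split
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating gene duplications relative to the split between
    jawless (cyclostome) and jawed (gnathostome) vertebrates from single-gene
    phylogenies.  A query gene (e.g. a lamprey paralog) is attached at every
    allowed branch of a constrained, event-labelled backbone gene tree; each
    candidate topology is scored by fixed-topology maximum likelihood under
    empirical amino-acid substitution models (JTT, LG, with gamma rate
    variation and invariant sites), topologies are weighted by normalized
    likelihood or RELL bootstrap proportions, and duplication events are
    classified as before or after the split to give probabilistic duplication
    counts.  A companion set of coding-sequence diagnostics computes GC3,
    Wright's effective number of codons, relative synonymous codon usage, and
    correspondence / within-group correspondence analysis of codon and
    amino-acid composition.  Seeded simulators for alignments evolved along a
    known gene tree and for codon sets with a controllable GC3 target make
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
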