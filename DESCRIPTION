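Package: treecord
Title: Topological Congruence, Consensus and Combinability of Phylogenetic
    Tree Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying agreement between phylogenetic trees and
    tree samples, as used in meta-analyses comparing molecular and
    morphological estimates of phylogeny. Implements Robinson-Foulds and
    quartet distances normalised by the maximum attainable distance given
    the resolution of both trees, an asymmetric proportional-congruence
    statistic for comparing partially resolved query trees against a fully
    resolved reference, consensus construction (strict, majority-rule,
    all-compatible) with support annotation and iterative support-threshold
    collapse scans, maximum clade credibility tree selection, classical
    multidimensional scaling of pooled tree-to-tree distance matrices
    (treespace ordination), Bayes-factor combinability verdicts from
    stepping-stone marginal-likelihood estimates, and seeded generators of
    synthetic tree clouds and two-partition conflict scenarios for testing
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
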