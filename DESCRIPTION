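Package: splitcover
Title: Gene-Tree Sample Sizes for Bipartition Covers Under the
    Multispecies Coalescent
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical machinery for deciding how many gene trees are
    needed before every nontrivial split (bipartition) of a species tree
    is likely to appear in a random gene-tree sample under the
    multispecies coalescent. Provides a numerically robust evaluation of
    the Kingman lineage-counting probability g[i,j](T), exact
    bipartition-cover probabilities for four-taxon species trees, a
    general Bonferroni-type lower bound on the cover probability together
    with its inversion into an upper bound on the required number of
    loci, Yule-process theory for the minimum internal branch length, and
    a stochastic multispecies-coalescent gene-tree simulator used to
    validate the bound empirically. Relevant to summary species-tree
    methods such as ASTRAL whose search space is built from observed gene
    tree bipartitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
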