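Package: dendrocare
Title: Comparative Phylogenetics of Aposematism and Parental Care in Poison Frogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether aposematism (conspicuous coloration and
    skin-alkaloid defenses) evolves in a correlated fashion with parental-care
    strategies such as phytotelm breeding on a time-calibrated phylogeny.
    Implements trait scoring and binarization rules for dendrobatid-style
    species tables, equal-rates Mk likelihoods and marginal ancestral state
    reconstruction, Pagel-style independent and dependent models for pairs of
    binary traits with maximum-likelihood and Bayesian fitting, stepping-stone
    marginal likelihoods and log Bayes factors, phylogenetic generalized least
    squares, Bayesian phylogenetic logistic regression with a species-level
    random effect, and a seed-deterministic synthetic-data generator that
    emulates the statistical structure of a dendrobatid trait dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    nlme,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    coda,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
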