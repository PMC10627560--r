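Package: cladsmc
Title: Data-Augmented Bayesian Inference Under the ClaDS Diversification Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the cladogenetic diversification rate shift (ClaDS)
    birth-death model as a tree prior inside a self-contained Bayesian
    phylogenetic inference engine. Every edge of the phylogeny carries its own
    birth and death rates, inherited at speciation events through a lognormal
    kernel with a trend parameter and a variance parameter. Inference uses
    data augmentation: the Markov chain explores the joint space of the
    reconstructed tree, the scalar model parameters, and the hidden (extinct
    or unsampled) parts of the complete tree, which are resimulated by
    Gillespie forward sampling inside Metropolis-Hastings operators
    (augmented Wilson-Balding, subtree exchange, node shift, and subtree
    resimulation). The package includes a forward simulator of complete and
    reconstructed trees, a minimal JC69 strict-clock alignment likelihood for
    full inference, tree-shape statistics (gamma statistic, Colless index),
    and a sampling-from-prior validation harness that compares the MCMC
    against forward simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
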