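Package: rhpcbn
Title: Constraint-Based Bayesian Network Structure Learning with RHPC
Version: 0.1.0
Authors@R: person("pkg", "maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based Bayesian network structure learning built around
    the Hybrid Parents and Children (HPC) local discovery algorithm and its
    recursive, whole-network form (RHPC).  Provides conditional-independence
    tests (G2 / Pearson chi-squared for discrete data, Fisher's z for
    continuous data, and a d-separation oracle), the Inter-IAMB Markov
    boundary learner and the Inter-IAPC parents-and-children learner, the
    data-efficient DE-PCS and DE-SPS superset filters, essential-graph
    (CPDAG) computation with Meek-rule orientation propagation, bootstrap
    consensus-network aggregation with directional edge confidences, forward
    sampling from discrete Bayesian networks, a BIF reader/writer, and a
    structure-recovery benchmark harness with the (1-precision)^2 +
    (1-recall)^2 distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
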