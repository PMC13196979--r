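Package: ndgpmap
Title: Non-Deterministic Genotype-Phenotype Maps: Synthetic and Biophysical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and characterising non-deterministic (ND)
    genotype-phenotype (GP) maps, in which each genotype maps to a probability
    ensemble over phenotypes rather than a single categorical phenotype.
    Provides a tuneable synthetic map generator combining additive
    genotype-dependent scalars with Boltzmann-like (and five alternative)
    nonlinearities, exhaustive builders for two biophysical reference maps
    (the 4x4 HP lattice protein and stochastic Polyomino tile self-assembly),
    an optional RNA secondary-structure adapter with an injected free-energy
    evaluator, and the full ND property suite: phenotypic frequency, genotypic
    and phenotypic robustness and evolvability, mutational-neighbour covariance
    diagnostics, the genotypic robustness-evolvability trade-off bound, and
    map-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
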