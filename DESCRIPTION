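Package: ptadsuite
Title: Preserved TADs After Cohesin Depletion: Copolymer Simulation and
    3D-Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying why a subset of topologically associating
    domains (TADs) survives cohesin depletion. Implements a chromosome
    copolymer model (A/B-typed self-avoiding chain with FENE bonds,
    Lennard-Jones type-dependent attractions and harmonic CTCF loop
    restraints) integrated with Langevin dynamics; contact-map analytics
    (distance-stratified Z-scores, Pearson correlation maps,
    Kullback-Leibler divergence, PC1 compartments, Ward linkage matrices,
    contact/distance power-law conversion); a TopDom-style TAD caller with
    preserved-TAD matching and epigenetic-switch classification;
    single-structure spatial boundary strengths, ensemble boundary
    probabilities and DBSCAN cluster statistics; and a maximum-entropy
    generator of 3D structure ensembles from contact maps alone. Synthetic
    chromosome generators with known ground truth make the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
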