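Package: fluxmodules
Title: Modularity of Sampled Metabolic Networks via Fully Coupled Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how environmental versatility shapes the modular
    organization of genome-scale metabolic networks. Provides a plain-text
    stoichiometric model format with readers and writers, flux balance
    analysis on a built-in bounded-variable simplex solver, flux variability
    and blocked-reaction detection, flux coupling analysis with partitioning
    of reactions into fully coupled sets and the modularity indices M and s,
    Markov chain Monte Carlo sampling of viable reaction-set genotypes at
    fixed network size under one or more minimal growth environments,
    network-expansion (scope) distances of reactions from nutrients, pathway
    coherence statistics (Q, h-index) with an annotation-swap randomization
    test, and an orchestration layer for versatility-versus-modularity
    experiments on synthetic reaction universes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
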