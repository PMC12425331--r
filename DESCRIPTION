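Package: commutebrain
Title: Commute-Time Communication Models for Brain Structure-Function Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Computes commute time and competing communication metrics
    (hitting time, mean-first-passage-time commute, communicability,
    search information, resistance distance) from weighted structural
    connectomes via the graph Laplacian pseudoinverse, simulates
    resting-state-like function with a mean-field Ising model on the same
    structure (Metropolis-Hastings spin dynamics, hemodynamic response
    convolution, Pearson functional connectivity), and quantifies how
    well each structural metric explains functional connectivity,
    including principal-mode truncation, shuffled-structure nulls,
    homotopic tract perturbations, and higher-order non-backtracking
    random-walk validation. Ships a synthetic connectome generator
    emulating diffusion-MRI-derived tract-count matrices with two
    hemispheric blocks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
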