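Package: rpni
Title: Regulation-Pattern-Guided Inference of Gene Regulatory Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs undirected gene regulatory network skeletons from
    steady-state expression data with a path-consistency algorithm driven by
    conditional mutual inclusive information (CMI2) under a multivariate
    Gaussian model.  Conditioning genes for each edge are restricted to
    biologically motivated candidate patterns (co-regulation, indirect
    regulation and their mixture) detected from knockout experiments via
    z-tests, which prunes the search space of the classical PC loop.  Includes
    confusion-matrix and ROC/AUC benchmarking against gold-standard edge
    lists, a linear-Gaussian steady-state simulator with planted regulatory
    motifs and null-mutant (knockout) designs, and the noise-corruption models
    used for robustness analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), igraph, jsonlite, MASS, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
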