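Package: molgvae
Title: Non-Autoregressive Conditional Graph Variational Autoencoder for
    Molecular Graph Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a conditional variational autoencoder that emits an entire
    molecular graph (atoms, charges, explicit hydrogens, bonds) in a single
    non-autoregressive decoder pass. Training combines an approximate
    graph-matching reconstruction loss based on permutation-invariant count
    profiles, a deterministic policy-gradient reward network that steers the
    decoder toward chemically valid molecules, and an auxiliary property
    predictor for molecular weight and Wildman-Crippen LogP. Includes
    property-conditioned generation via Gaussian conditioning of the property
    prior, generation quality metrics (validity, uniqueness, novelty, G-mean),
    a synthetic small-molecule fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
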