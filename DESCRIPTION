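Package: ribowalk
Title: Stochastic Random-Walk Model of Translational Elongation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models translational elongation as a unidirectional
    continuous-time random walk of the lead ribosome on a codon lattice with
    site-specific random rate constants and an optional ribosome-recycling
    (circular template) step. Provides the generator and transition matrices,
    four cross-validated propagator algorithms (matrix exponential,
    closed-form open-chain sum, divided differences via the Opitz bidiagonal
    form, and a spectral residue expansion for the circular chain), the
    Laplace-domain operator for transcripts undergoing first-order decay,
    closed-form steady-state and per-template statistics (polypeptides and
    ribosomes per transcript, expected chain length), a greedy codon
    optimization heuristic, ensemble simulation of protein-output
    distributions across cell populations, and a distribution-fitting layer
    (maximum-likelihood single-family and two-component mixture fits,
    BIC model selection, quantile-quantile diagnostics, tail-deviation
    metrics) used to characterize the approximately log-normal protein
    abundance distributions the model produces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
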