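Package: desvisc
Title: Sigma-Profile Neural Network Modelling of Deep Eutectic Solvent Viscosity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structure-property modelling of the viscosity of
    choline-chloride deep eutectic solvents and their cosolvent mixtures.
    Discretizes COSMO-type sigma-profiles into eight charge-density region
    areas (S1..S8), combines them into mole-fraction-weighted mixture
    descriptors, and fits a feed-forward neural network with Bayesian
    regularization that predicts log10 viscosity from the eight descriptors
    and temperature. Includes ordered-response data splitting, fit statistics
    (R2, RMSE, AARD), leave-one-system-out cross-validation, Williams-plot
    applicability-domain analysis, partial-derivative (PaD) input
    contributions, and a synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
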