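Package: nitrospec
Title: Nitrogen Deficiency Inversion from Hyperspectral Reflectance
    Differences in Rice Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates leaf nitrogen deficiency in japonica rice from
    hyperspectral reflectance differences taken against a max-yield
    "standard field" reference. Provides a seed-reproducible synthetic
    generator for leaf reflectance (401-1000 nm, 600 bands) under four
    nitrogen treatments, difference-spectrum construction against the
    highest-yield treatment, four dimensionality reductions (discrete
    wavelet multiscale decomposition, successive projections algorithm,
    principal component analysis, and iteratively retaining informative
    variables with synergy-interval PLS pre-screening), and three
    inversion regressors (partial least squares regression, extreme
    learning machine, and a genetic-algorithm-initialized extreme
    learning machine), with an experiment grid reporting R-squared and
    RMSE on train/validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
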