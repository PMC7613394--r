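Package: lutraits
Title: Crop Trait Retrieval from Canopy Spectra by Look-Up-Table
    Inversion and Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation-based comparison of retrieval strategies for leaf
    area index (LAI), fractional vegetation cover (fCover) and canopy
    chlorophyll content (CCC) of row crops from multispectral canopy
    reflectance. Implements standard and correlation-regularized look-up
    table (LUT) inversion driven by correlated Latin hypercube sampling
    with Cholesky-imposed trait correlations, hybrid machine-learning
    retrieval (random forest, Gaussian process regression, canonical
    correlation forest) trained on simulated spectra, in-situ random
    forest retrieval with an exposure-time covariate under
    leave-one-date-out validation, empirical line calibration, and a
    synthetic field-campaign generator that emulates a six-date potato
    fertilization trial under variable illumination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    lhs,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
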