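Package: aquafluct
Title: Density Fluctuations and Structural Heterogeneity in Supercooled
    Aqueous Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for supercritical density fluctuations in
    supercooled dilute aqueous solutions (e.g. glycerol-water microdroplets).
    Computes radial distribution functions and X-ray structure factors S(q)
    from periodic particle configurations, decomposes small-angle scattering
    into a Percus-Yevick hard-sphere background plus an Ornstein-Zernike
    anomalous component, converts S(0) and NPT volume fluctuations into
    isothermal compressibilities, fits critical power laws with a divergence
    temperature and runs the goodness-of-fit exclusion scan used to flag
    Widom-line deviations, classifies high- and low-density-liquid-like water
    via the local structure index (LSI), and models Knudsen evaporative
    cooling of microdroplets in vacuum. A synthetic-data module generates
    every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
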