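Package: steppediv
Title: Multi-Scale Spatial Analysis of Plant Diversity in Quadrat-Grid Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing spatial patterns of plant species diversity in
    gridded quadrat surveys of grazed and fenced grassland, built around three
    questions: how diversity accumulates with sampling area (diversity-area
    curves fitted with power, exponential, logistic and parabolic models, plus
    a random-placement null model), how diversity is spatially structured
    (empirical semivariograms with exponential, spherical and Gaussian model
    fits), and how much of the variation is attributable to measured
    environment versus space (PCNM spatial eigenvectors, permutation-based
    forward selection, and adjusted R-squared variance partitioning). A
    synthetic community generator with spatially autocorrelated environment
    and treatment effects allows the full pipeline to run and be tested
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    generics,
    yaml,
    ggplot2,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    vegan,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
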