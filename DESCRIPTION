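Package: prolifr
Title: Extended Logistic Modelling of Cell Proliferation with Correlated Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling intercellular-interaction-induced cell
    proliferation with an extended logistic growth law featuring a
    density-dependent intrinsic proliferation rate, an allometric crowding
    exponent, and density-regulated negative feedback from growth-inhibiting
    molecules. Provides equilibrium and stability analytics (conditional
    threshold density, maximum sustainable stable cell density, inflection
    points, closed-form approximations), Fisher relative-growth-rate profile
    construction and exhaustive grid-search fitting to scratch-assay style
    time series, the stochastic analog of the growth law with correlated
    multiplicative and additive Gaussian white noise (noise-induced drift and
    diffusion, stationary Fokker-Planck densities, stochastic carrying
    density approximations), ensemble stochastic simulation with steady-state
    mode classification, and a synthetic scratch-assay data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
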