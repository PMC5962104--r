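Package: debfit
Title: Dynamic Energy Budget Life-Cycle Simulation and Parameter Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the standard Dynamic Energy Budget (DEB) model and its
    typified extensions (fetal development, metabolic acceleration,
    holometabolous life cycles) from the start of embryo development to death
    by aging, and estimates the primary DEB parameters of a species from
    heterogeneous zero- and uni-variate eco-physiological data. Estimation
    uses symmetric bounded loss functions, automatic weights, pseudo-data
    priors and a feasibility-filtered Nelder-Mead simplex with continuation.
    Includes goodness-of-fit metrics (mean relative error, symmetric mean
    squared error), a data-completeness score, a synthetic-entry generator,
    and cross-species comparison utilities based on parameter covariation
    with a dimensionless zoom factor.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
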