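Package: rajastat
Title: Conservation and Exploitation Status Assessment for Data-Poor Skate Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dual assessment of skate (Rajidae) populations from
    mitochondrial COI barcodes and data-poor fisheries data. Implements
    haplotype and nucleotide diversity estimation with Nei's variance
    estimators, a Mediterranean-Atlantic comparative diversity framework with
    percentile-bootstrap median confidence intervals and population
    classification, horsepower-standardized fishing effort and CPUE series,
    VMS-based allocation of fishing days to bathymetric strata, a Bayesian
    state-space Schaefer surplus-production model with Kobe-quadrant posterior
    probabilities, and length-based Bayesian biomass estimation (LBB) from
    stratified trawl-survey length frequencies. Seeded synthetic-data
    generators with ground-truth labels support simulation-based validation
    of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
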