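Package: noxsource
Title: Isotope Mass-Balance Source Apportionment of Atmospheric NOx
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for partitioning nitrogen oxide (NOx) emissions among
    fossil and non-fossil sources from natural-abundance nitrogen isotope
    ratios of nitrate in precipitation. Reconstructs the d15N of the
    initial atmospheric NOx pool from ambient NO2, HNO3 and particulate
    nitrate, estimates the isotope offset between initial NOx and
    precipitation nitrate, fits a Bayesian isotope mixing model with a
    Dirichlet prior on the source-fraction simplex (random-walk Metropolis
    on an additive-log-ratio transform), aggregates urban and non-urban
    contributions with population weights, and converts inventory
    fossil-fuel emission amounts into total and non-fossil emission
    budgets with Monte Carlo uncertainty propagation. Includes a
    synthetic-data generator for end-to-end testing and descriptive
    statistics (group comparisons and temporal trends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
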