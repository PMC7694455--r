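Package: phenokit
Title: Thermal-Time Analysis of Grass Weed Emergence, Growth, Phenology,
    Fecundity and Crop Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for field and greenhouse studies of annual
    grass weeds (Vulpia myuros and related species) growing in monoculture and
    in winter wheat. Converts daily weather to cumulative thermal time (growing
    degree days above a base temperature); fits two-parameter log-logistic
    cumulative-emergence curves to grouped inspection counts by maximum
    likelihood (time-to-event approach) with delta-method emergence quantiles
    (GERM10/50/90); fits Weibull and log-logistic biomass-accumulation curves
    with lack-of-fit checks, TIME50 and crop-suppression ratios of total
    biomass; compares interval-censored BBCH stage-attainment times between
    species with a Monte-Carlo imputation-permutation test and nonparametric
    bootstrap confidence intervals; calibrates seeds-per-panicle against
    panicle length to estimate per-plant fecundity and tests crop suppression
    of seed production; and fits the two-parameter hyperbolic
    target-neighbourhood competition model with DENS50 comparisons. A
    synthetic-data generator reproduces the distributional structure of all
    six input streams so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
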