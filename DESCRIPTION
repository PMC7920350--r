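Package: mobfit
Title: Fitting Fine-Scale Human Mobility Models to Aggregated Flow Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fitting fine-scale gravity and radiation models of
    human mobility to origin-destination trip counts that are only observed
    at an aggregated (administrative-unit) spatial scale. Provides gridded
    population preprocessing (multi-scale grids, population-weighted
    centroids, cell-to-unit assignment, small-unit merging), gravity and
    four radiation model kernels with cell-to-admin flow aggregation, a
    negative binomial likelihood for over-dispersed count data, Latin
    hypercube seeded adaptive Metropolis MCMC with split R-hat convergence
    assessment, posterior-predictive flow summaries, trip-distance profiles
    with power-law fits, an origin-destination symmetry diagnostic, and a
    synthetic-data generator emulating clustered and dispersed population
    settings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
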