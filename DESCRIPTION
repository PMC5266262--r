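Package: foragedist
Title: Seabird Foraging Distribution Models and Spatial Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models at-sea foraging distributions of nonresident seabirds
    from binned strip-transect survey counts. Provides seeded synthetic
    survey, grid and climate-index generators; engineered covariates
    (seafloor contour index, lagged climate indices, ordinary kriging of
    shipboard oceanographic fields with a surface quality filter, and
    regression gap-filling of missing underway records); negative binomial
    and zero-inflated negative binomial count regressions with survey-area
    offsets, over-dispersion and Vuong tests; a two-stage univariate and
    backward-stepwise model-selection protocol; repeated k-fold
    cross-validation; gridded abundance prediction with standardization and
    percent ranking; an adapted Cramer-von Mises randomization test for
    comparing two gridded distributions; and a simulated-annealing
    minimum-set reserve selector with a boundary-length penalty and
    species penalty factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    glmmTMB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
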