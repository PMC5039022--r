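Package: srftrends
Title: Population Trend Analysis for Aerial Strip-Transect Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design-based abundance estimation and semiparametric trend
    modelling for systematic reconnaissance flight (SRF) monitoring data on
    rangeland wildlife and livestock.  Provides Jolly's Method 2 ratio
    estimator with finite-population-corrected variance for transects of
    unequal length; a multivariate semiparametric negative-binomial mixed
    model in which penalized B-spline (P-spline) trends common to all species
    and specific to each species enter as random effects, fitted by penalized
    quasi-likelihood; prediction of unsurveyed years with pointwise 95%
    confidence bands; aggregation of county series to regional totals, period
    averages, percentage changes and biomass summaries; intercensal
    exponential interpolation of human population; climate trend tests;
    negative-binomial density-covariate regressions with AICc shape selection
    and forward model selection under strong hierarchy; and a synthetic
    survey generator that emulates the statistical structure of the SRF
    design for testing every stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: MASS, splines, stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), minpack.lm, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
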