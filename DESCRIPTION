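Package: transectvar
Title: Variance Partitioning and Precision Analysis for Repeated Video
    Transect Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the methodological assessment of repeated video
    transect surveys of reef fish assemblages. Implements a hierarchical
    synthetic-data generator (nested spatial factors, crossed observers,
    temporally ordered repeats, Conway-Maxwell-Poisson counts, schooling,
    turbidity-dependent detectability), diagnostics for temporal dependence
    and observer effects (per-species autocorrelation functions, binomial
    mixed models for detection order, partial Mantel correlograms),
    Monte-Carlo pooling of observations to quantify design error,
    univariate variance partitioning with intraclass correlation
    decomposition (linear mixed models and zero-inflated
    Conway-Maxwell-Poisson mixed models), balanced mixed-model PERMANOVA
    with expected-mean-square components of variation, canonical analysis
    of principal coordinates with leave-one-out cross-validation, and
    precision analysis (standard-error-to-mean ratios and multivariate
    pseudo standard errors) as functions of repeats and transect length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    glmmTMB,
    vegan,
    MASS,
    jsonlite,
    yaml,
    rlang,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
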