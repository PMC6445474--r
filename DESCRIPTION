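Package: stagedist
Title: Life-Stage Distribution Modelling from Bottom-Trawl Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes bottom-trawl survey catches into life-stage catch per
    unit effort (CPUE) with logistic sex-maturity-age-length-key models,
    fits zero-altered Poisson hurdle generalised additive mixed models of
    density on environmental covariates, and classifies the predicted
    surfaces into aggregated and dispersed space use with geostatistical
    aggregation curves, slope-1 tangent thresholds and multi-year
    persistence maps. Ships a synthetic-survey generator with exported
    ground truth so every stage of the pipeline can be tested without
    access to survey databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    geosphere,
    glmmTMB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
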