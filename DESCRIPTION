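Package: howlspot
Title: Acoustic Localization Surveys with Low-Density Microphone Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design, simulate and evaluate large-scale acoustic
    localization campaigns of the kind used to monitor vocal wildlife such as
    the grey wolf (Canis lupus): synthetic howl-like sweep generation and
    rendering into noisy recordings, template cross-correlation onset (time of
    arrival) extraction, a field-campaign simulator (regular recorder grid,
    stratified broadcast sites, Latin-square night/period schedule,
    distance-dependent detection and signal-to-noise, temperature-dependent
    sound speed, Gaussian TOA noise), a time-of-arrival least-squares
    localization solver with a pairwise temporal-error reliability statistic
    and threshold filter, and an evaluation stage computing localization
    accuracy, geometric covariates and an AIC comparison of linear accuracy
    models.
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
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    utils,
    tibble,
    tidyr,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
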