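Package: svycoxsim
Title: Simulation of Survey-Weighted Cox Models Under Stratified Sampling and Loss to Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study the impact of non-proportional stratified sampling
    and loss to follow-up on Cox proportional-hazards estimation. Generates a
    synthetic occupational cohort with Weibull proportional-hazards event
    times, draws simple-random and stratified samples with design weights,
    imposes random or stratum-differential attrition, fits weighted and
    unweighted Cox models of several specifications with a native weighted
    partial-likelihood solver and design-based (sandwich) variance, and
    summarises bias, variance and mean squared error of hazard-ratio
    estimates over Monte-Carlo replicates.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
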