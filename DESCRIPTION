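Package: envexcess
Title: Excess Mortality Estimation with Enveloping Prediction Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates excess mortality from stratified vital-registration
    death counts. Expected (counterfactual) deaths for a target year are
    forecast per country, sex and age group from a short window of reference
    years under three baseline models: the over-dispersed Poisson mean, the
    over-dispersed Poisson trend, and a Lee-Carter model adapted to death
    counts that pools the full age-sex-year matrix. The three forecasts are
    combined into a conservative enveloping interval (highest point estimate,
    lowest lower bound, highest upper bound), and excess deaths are the
    observed counts minus the envelope, with bounds obtained by subtracting
    the interval limits. Includes a synthetic vital-registration generator
    with configurable age schedules, secular trends, over-dispersion and
    crisis-year shocks, plus robustness and calibration harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
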