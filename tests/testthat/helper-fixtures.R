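# Shared fixtures: tiny registries and schemes built in code.

# compact 4-group scheme used by the calibration simulations
calibration_scheme <- function() {
  age_scheme(c(0, 15, 50, 65))
}

# zero-trend, no-shock scenario on the compact scheme; within all three
# model classes at once (constant mean, zero slope, rank-1 with flat kappa)
calibration_scenario <- function(base_level = 200, dispersion = 1.3,
                                 seed = 20200927) {
  scenario_config(
    country = "CAL",
    scheme = calibration_scheme(),
    years = 2015:2020,
    base_level = base_level,
    age_schedule = log(c(1, 1.5, 2, 6)),
    sex_log_ratio = log(1.4),
    annual_trend = 0,
    dispersion = dispersion,
    shocks = list(),
    seed = seed
  )
}

# small hand-written death table: one country, 2 strata, 5 + 1 years
tiny_death_table <- function(country = "TST") {
  tidyr::expand_grid(
    country = country,
    sex = c("female", "male"),
    age_group = "15-19",
    year = 2015:2020
  ) |>
    dplyr::mutate(deaths = c(10L, 12L, 9L, 11L, 10L, 13L, 20L, 22L, 19L, 21L, 20L, 60L))
}

# build a death_matrix directly from a counts matrix (bypasses CSV plumbing)
matrix_fixture <- function(counts, years = 2015:(2014 + ncol(counts)),
                           country = "FIX") {
  n <- nrow(counts)
  stopifnot(n %% 2 == 0)
  labels <- default_age_scheme()$label[seq_len(n / 2)]
  strata <- tidyr::expand_grid(sex = c("female", "male"), age_group = labels)
  structure(
    list(
      country = country, strata = strata, years = as.integer(years),
      counts = `dimnames<-`(counts, list(
        paste(strata$sex, strata$age_group, sep = "."), years
      ))
    ),
    class = "death_matrix"
  )
}
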