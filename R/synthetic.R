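#' Specify a crisis-year mortality shock
#'
#' A shock elevates expected deaths in one calendar year for a set of
#' sex/age strata. A `multiplicative` shock multiplies each targeted
#' stratum's expectation by `magnitude` (a rate ratio); an `additive` shock
#' adds `magnitude` expected deaths in total, apportioned across the
#' targeted strata proportionally to their baseline expectations.
#'
#' @param year Calendar year of the shock.
#' @param sexes Subset of `c("male", "female")`.
#' @param age_lower,age_upper Age range of targeted groups (whole groups
#'   only; `Inf` for the open-ended terminal group).
#' @param kind `"multiplicative"` or `"additive"`.
#' @param magnitude Rate ratio (> 0) or total added expected deaths (>= 0).
#' @return A `shock_spec` list.
#' @export
shock_spec <- function(year, sexes, age_lower, age_upper,
                       kind = c("multiplicative", "additive"), magnitude) {
  kind <- match.arg(kind)
  stopifnot(all(sexes %in% c("male", "female")), length(sexes) >= 1)
  if (kind == "multiplicative" && magnitude <= 0) {
    stop("multiplicative shock magnitude must be > 0", call. = FALSE)
  }
  if (kind == "additive" && magnitude < 0) {
    stop("additive shock magnitude must be >= 0", call. = FALSE)
  }
  structure(
    list(
      year = as.integer(year), sexes = sexes, age_lower = age_lower,
      age_upper = age_upper, kind = kind, magnitude = magnitude
    ),
    class = "shock_spec"
  )
}

#' Scenario configuration for a synthetic vital registry
#'
#' Defines the deterministic expected-death surface and the sampling noise
#' of a synthetic registry: a J-shaped age schedule of log-rate offsets
#' (elevated infant mortality, minimum in the school ages, roughly
#' log-linear rise thereafter), a male-excess log rate, a mild secular
#' trend, quasi-Poisson dispersion and a list of crisis-year shocks.
#'
#' @param country Country code for the generated rows.
#' @param scheme Active [age_scheme()].
#' @param years Calendar years to generate (default 2015:2020).
#' @param base_level Expected deaths in the reference stratum (female,
#'   first age group, first year).
#' @param age_schedule Per-group log offsets relative to the reference
#'   group; length must match the scheme.
#' @param sex_log_ratio Log of the male/female expected-death ratio.
#' @param annual_trend Log-linear drift per calendar year (e.g. -0.01 for a
#'   1\% annual mortality decline).
#' @param dispersion Variance-to-mean ratio of the counts (>= 1; 1 is exact
#'   Poisson).
#' @param shocks List of [shock_spec()] objects.
#' @param seed Integer seed used by [sample_registry()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(country = "SYN",
                            scheme = default_age_scheme(),
                            years = 2015:2020,
                            base_level = 150,
                            age_schedule = default_age_schedule_offsets(),
                            sex_log_ratio = log(1.4),
                            annual_trend = -0.01,
                            dispersion = 1.3,
                            shocks = list(),
                            seed = 20200927) {
  validate_age_scheme(scheme)
  if (length(age_schedule) != nrow(scheme)) {
    stop("age_schedule must have one offset per age group (",
      nrow(scheme), ")",
      call. = FALSE
    )
  }
  if (dispersion < 1) stop("dispersion must be >= 1", call. = FALSE)
  if (base_level <= 0) stop("base_level must be > 0", call. = FALSE)
  stopifnot(all(vapply(shocks, inherits, logical(1), "shock_spec")))
  structure(
    list(
      country = country, scheme = scheme, years = as.integer(years),
      base_level = base_level, age_schedule = age_schedule,
      sex_log_ratio = sex_log_ratio, annual_trend = annual_trend,
      dispersion = dispersion, shocks = shocks, seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Default J-shaped age schedule (log offsets, 16 groups)
#'
#' Offsets are relative to the infant group and emulate the death-count age
#' profile of a small-country registry: counts drop steeply after infancy,
#' reach their minimum in the school ages, then rise roughly log-linearly,
#' with the open-ended old-age group dominating.
#'
#' @return Numeric vector of length 16 (the [default_age_scheme()] order).
#' @export
default_age_schedule_offsets <- function() {
  # expected female deaths per group, per ~150 in the infant group
  levels <- c(
    150, 25, 12, 12, 20, 28, 35, 45, 65, 95,
    150, 240, 380, 600, 850, 8200
  )
  log(levels / levels[1])
}

#' Deterministic expected-death surface of a scenario
#'
#' Evaluates the scenario's expectation for every (sex, age group, year)
#' cell, applying shocks only in their year and strata. No randomness is
#' involved. An additive shock of magnitude E raises the total expectation
#' of its targeted strata by exactly E.
#'
#' @param config A [scenario_config()].
#' @return A tibble `country`, `sex`, `age_group`, `year`, `expected`.
#' @export
expected_surface <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  scheme <- config$scheme
  grid <- tidyr::expand_grid(
    sex = c("female", "male"),
    age_group = scheme$label,
    year = config$years
  )
  idx <- match(grid$age_group, scheme$label)
  log_mu <- log(config$base_level) +
    config$age_schedule[idx] +
    ifelse(grid$sex == "male", config$sex_log_ratio, 0) +
    config$annual_trend * (grid$year - min(config$years))
  grid$expected <- exp(log_mu)

  for (shock in config$shocks) {
    labels <- age_groups_in_range(scheme, shock$age_lower, shock$age_upper)
    hit <- grid$year == shock$year & grid$sex %in% shock$sexes &
      grid$age_group %in% labels
    if (!any(hit)) {
      stop("shock in ", shock$year, " targets no stratum", call. = FALSE)
    }
    if (shock$kind == "multiplicative") {
      grid$expected[hit] <- grid$expected[hit] * shock$magnitude
    } else {
      base <- grid$expected[hit]
      grid$expected[hit] <- base + shock$magnitude * base / sum(base)
    }
  }
  tibble::tibble(country = config$country, grid)
}

#' Sample a synthetic death registry
#'
#' Draws every cell's count independently from a negative binomial with
#' mean equal to the scenario's expected surface and variance
#' `dispersion * mean` (exact Poisson at dispersion 1). Reproducible under
#' the scenario seed.
#'
#' @param config A [scenario_config()].
#' @param seed Overrides `config$seed` if given.
#' @param exposure If `TRUE`, also attach a constant population-exposure
#'   table (attribute `"exposure"`) sized so that the registry's crude
#'   death rate is plausible; used by the rates-variant tests.
#' @return A tidy death table (`country`, `sex`, `age_group`, `year`,
#'   `deaths`), validated against the scenario scheme.
#' @examples
#' reg <- sample_registry(karabakh_preset())
#' dplyr::count(reg, year, wt = deaths)
#' @export
sample_registry <- function(config, seed = NULL, exposure = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  surface <- expected_surface(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  draw <- function() {
    rcount_overdispersed(nrow(surface), surface$expected, config$dispersion)
  }
  counts <- withr::with_seed(seed, draw())
  out <- dplyr::mutate(
    dplyr::select(surface, -"expected"),
    deaths = as.integer(counts)
  )
  out <- validate_death_table(out, config$scheme)
  if (exposure) {
    # population ~ 100x the annual expected deaths in each stratum, constant
    # over years: crude rates of order 1%
    pop <- dplyr::summarise(
      dplyr::group_by(surface, .data$country, .data$sex, .data$age_group),
      population = 100 * mean(.data$expected), .groups = "drop"
    )
    exp_tbl <- dplyr::cross_join(pop, tibble::tibble(year = config$years))
    attr(out, "exposure") <- validate_exposure_table(
      dplyr::select(
        exp_tbl, "country", "sex", "age_group", "year", "population"
      ),
      config$scheme
    )
  }
  out
}

#' Conflict-plus-pandemic preset scenario
#'
#' A registry at the scale of a small country (roughly 23,000 deaths per
#' year) with two 2020 shocks: an additive conflict shock of 1,000 expected
#' deaths apportioned over males aged 15-49, and a multiplicative pandemic
#' shock (rate ratio 1.25) for both sexes aged 60 and over. The conflict
#' magnitude and its concentration in fighting-age men mirror the pattern a
#' short high-intensity war leaves in annual registration data; the old-age
#' shock mimics a first pandemic wave.
#'
#' @param conflict_deaths Additive conflict-shock magnitude (default 1000).
#' @param pandemic_ratio Multiplicative old-age shock (default 1.25).
#' @param seed Scenario seed.
#' @return A [scenario_config()].
#' @export
karabakh_preset <- function(conflict_deaths = 1000, pandemic_ratio = 1.25,
                            seed = 20200927) {
  shocks <- list()
  if (conflict_deaths > 0) {
    shocks <- c(shocks, list(
      shock_spec(2020, "male", 15, 49, "additive", conflict_deaths)
    ))
  }
  if (pandemic_ratio != 1) {
    shocks <- c(shocks, list(
      shock_spec(2020, c("male", "female"), 60, Inf, "multiplicative", pandemic_ratio)
    ))
  }
  scenario_config(country = "SYN", shocks = shocks, seed = seed)
}

#' Small-population preset (tens of deaths per year)
#'
#' Scales the default scenario down by a factor of ~75 so that many strata
#' have single-digit or zero counts, exercising the zero-count paths
#' (Lee-Carter log offsets, all-zero series conventions) that tiny
#' registries hit in practice.
#'
#' @param conflict_deaths Additive conflict-shock magnitude (default 60).
#' @param seed Scenario seed.
#' @return A [scenario_config()].
#' @export
artsakh_preset <- function(conflict_deaths = 60, seed = 20200927) {
  shocks <- list()
  if (conflict_deaths > 0) {
    shocks <- list(shock_spec(2020, "male", 15, 49, "additive", conflict_deaths))
  }
  scenario_config(
    country = "SML", base_level = 2, shocks = shocks, seed = seed
  )
}
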