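#' Build a pipeline run configuration
#'
#' Bundles and validates everything an end-to-end run needs: the input
#' death table (tibble or CSV path), the reference window and target year,
#' model options and the reporting age range.
#'
#' @param input A death table tibble or a CSV path readable by
#'   [read_death_table()]. Must contain the reference years and the target
#'   year.
#' @param exposure Optional exposure tibble or CSV path (required for
#'   `mode = "rates"`).
#' @param scheme Active [age_scheme()].
#' @param reference_years Reference window (default 2015:2019).
#' @param target_year Forecast year (default 2020); must not be a reference
#'   year.
#' @param models Models to fit (default all three).
#' @param mode `"counts"` or `"rates"`.
#' @param exclude_years Years dropped from the reference window.
#' @param age_range Reporting age range `c(lower, upper)` aligned with the
#'   scheme (default `c(15, 49)`).
#' @param level Predictive-interval level.
#' @param seed Integer seed for all interval simulations.
#' @param pi_draws Simulation draws per interval.
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   `estimates.csv`, `aggregates.csv`, `table1.csv` and `manifest.json`
#'   there.
#' @return A `run_config` list.
#' @export
run_config <- function(input, exposure = NULL, scheme = default_age_scheme(),
                       reference_years = 2015:2019, target_year = 2020L,
                       models = c("OPM", "OPT", "LC"),
                       mode = c("counts", "rates"), exclude_years = integer(),
                       age_range = c(15, 49), level = 0.95,
                       seed = 20201127, pi_draws = 1e5, output_dir = NULL) {
  mode <- match.arg(mode)
  if (target_year %in% setdiff(reference_years, exclude_years)) {
    stop("target year must not be in the reference window", call. = FALSE)
  }
  # fails early if the range splits a group
  age_groups_in_range(scheme, age_range[1], age_range[2])
  if (mode == "rates" && is.null(exposure)) {
    stop("rates mode requires an exposure table", call. = FALSE)
  }
  structure(
    list(
      input = input, exposure = exposure, scheme = scheme,
      reference_years = as.integer(reference_years),
      target_year = as.integer(target_year), models = models, mode = mode,
      exclude_years = as.integer(exclude_years), age_range = age_range,
      level = level, seed = as.integer(seed), pi_draws = pi_draws,
      output_dir = output_dir
    ),
    class = "run_config"
  )
}

resolve_table <- function(x, scheme, reader) {
  if (is.character(x)) reader(x, scheme) else reader_validate(x, reader, scheme)
}

reader_validate <- function(x, reader, scheme) {
  if (identical(reader, read_death_table)) {
    validate_death_table(x, scheme)
  } else {
    validate_exposure_table(x, scheme)
  }
}

#' Run the excess-mortality pipeline end to end
#'
#' Fit the three baseline models for every country in the input, combine
#' them into the enveloping interval, subtract from the observed
#' target-year counts, and aggregate over the reporting age range. The run
#' is deterministic under the configured seed. When `output_dir` is set,
#' the per-stratum estimates, the aggregates, the country-by-sex summary
#' table and a machine-readable manifest are written there.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `estimates` (per stratum x model),
#'   `envelope`, `excess` (per stratum), `aggregates` (country x sex over
#'   the age range), `table1` (formatted summary) and `manifest`.
#' @examples
#' reg <- sample_registry(karabakh_preset())
#' res <- run_pipeline(run_config(reg, pi_draws = 2000, seed = 7))
#' res$table1
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scheme <- config$scheme
  tbl <- resolve_table(config$input, scheme, read_death_table)
  exposure <- if (!is.null(config$exposure)) {
    resolve_table(config$exposure, scheme, read_exposure_table)
  }
  countries <- sort(unique(tbl$country))

  estimates <- dplyr::bind_rows(lapply(seq_along(countries), function(i) {
    fit_all(tbl, countries[i],
      target_year = config$target_year,
      reference_years = config$reference_years,
      exclude_years = config$exclude_years, models = config$models,
      mode = config$mode, exposure = exposure, scheme = scheme,
      level = config$level, pi_draws = config$pi_draws,
      seed = config$seed + i - 1L
    )
  }))
  envelope <- combine_envelope(estimates)
  observed <- dplyr::filter(tbl, .data$year == config$target_year)
  if (nrow(observed) == 0) {
    stop("input has no rows for target year ", config$target_year, call. = FALSE)
  }
  excess <- compute_excess(observed, envelope)
  aggregates <- aggregate_excess(excess,
    by = c("country", "sex"),
    age_range = config$age_range, scheme = scheme
  )
  tab1 <- table1_report(excess, age_range = config$age_range, scheme = scheme)

  manifest <- list(
    package = "envexcess",
    version = as.character(utils::packageVersion("envexcess")),
    countries = countries,
    reference_years = setdiff(config$reference_years, config$exclude_years),
    exclude_years = config$exclude_years,
    target_year = config$target_year,
    models = config$models,
    mode = config$mode,
    age_range = config$age_range,
    level = config$level,
    seed = config$seed,
    pi_draws = config$pi_draws
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    est_out <- dplyr::select(
      dplyr::rename(excess, excess_lo = "lo", excess_hi = "hi"),
      "country", "sex", "age_group", "observed", "expected", "expected_lo",
      "expected_hi", "excess", "excess_lo", "excess_hi", "argmax_model"
    )
    utils::write.csv(est_out, file.path(config$output_dir, "estimates.csv"),
      row.names = FALSE, quote = FALSE
    )
    utils::write.csv(aggregates, file.path(config$output_dir, "aggregates.csv"),
      row.names = FALSE, quote = FALSE
    )
    utils::write.csv(tab1, file.path(config$output_dir, "table1.csv"),
      row.names = FALSE, quote = TRUE
    )
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(list(
    estimates = estimates, envelope = envelope, excess = excess,
    aggregates = aggregates, table1 = tab1, manifest = manifest
  ))
}

#' Robustness variants of a pipeline run
#'
#' Re-runs the pipeline under the standard robustness arms — dropping an
#' anomalous reference year (default 2016) and switching to death rates —
#' and compares the grand-total excess over the reporting age range against
#' the baseline arm.
#'
#' @param config A [run_config()] for the baseline arm.
#' @param exclude_year Reference year to drop in the exclusion arm.
#' @param arms Arms to run, subset of
#'   `c("baseline", "exclude_year", "rates")`.
#' @return A tibble with one row per arm: `arm`, `excess`, `lo`, `hi`,
#'   `abs_diff`, `rel_diff` (differences of the point vs baseline).
#' @export
robustness_suite <- function(config, exclude_year = 2016L,
                             arms = c("baseline", "exclude_year", "rates")) {
  stopifnot(inherits(config, "run_config"))
  arms <- match.arg(arms, several.ok = TRUE)
  if ("rates" %in% arms && is.null(config$exposure)) {
    stop("rates arm requires an exposure table in the run config", call. = FALSE)
  }

  run_total <- function(cfg) {
    res <- run_pipeline(cfg)
    aggregate_excess(res$excess,
      by = character(), age_range = cfg$age_range,
      scheme = cfg$scheme
    )
  }
  out <- list()
  base_total <- NULL
  if ("baseline" %in% arms) {
    base_total <- run_total(config)
    out$baseline <- base_total
  }
  if ("exclude_year" %in% arms) {
    cfg <- config
    cfg$exclude_years <- unique(c(cfg$exclude_years, as.integer(exclude_year)))
    out$exclude_year <- run_total(cfg)
  }
  if ("rates" %in% arms) {
    cfg <- config
    cfg$mode <- "rates"
    out$rates <- run_total(cfg)
  }
  res <- dplyr::bind_rows(out, .id = "arm")
  res <- dplyr::select(res, "arm", "excess", "lo", "hi")
  if (!is.null(base_total)) {
    res$abs_diff <- res$excess - base_total$excess
    res$rel_diff <- ifelse(base_total$excess == 0, NA_real_,
      res$abs_diff / base_total$excess
    )
  }
  res
}

#' Simulation study of interval calibration and excess recovery
#'
#' Repeatedly samples registries from a scenario, fits the three models and
#' the envelope on the reference years, and measures (a) how often each
#' predictive interval covers the held-out target-year count in strata
#' untouched by target-year shocks, (b) the mean bias of the expected-death
#' points against the scenario's no-shock expectation, and (c) how well the
#' aggregated envelope excess recovers any additive shock.
#'
#' @param scenario A [scenario_config()].
#' @param replicates Number of simulated registries (>= 50).
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param pi_draws Simulation draws per interval (smaller than the
#'   single-run default — quantile noise averages out over replicates).
#' @param age_range Aggregation range for the shock-recovery summary.
#' @param models Models to fit.
#' @return A list of class `calibration_study`: `coverage` (tibble with
#'   `model`, `coverage`, `mean_bias`, `n`), `excess` (tibble with per-sex
#'   aggregated excess mean, Monte-Carlo SE, the share of replicates whose
#'   aggregated excess interval contains 0, and the true injected shock)
#'   and `replicates`.
#' @export
calibration_study <- function(scenario, replicates, seed = 1L,
                              pi_draws = 2000, age_range = c(15, 49),
                              models = c("OPM", "OPT", "LC")) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (replicates < 50) stop("replicates must be >= 50", call. = FALSE)
  target_year <- max(scenario$years)
  ref_years <- setdiff(scenario$years, target_year)
  scheme <- scenario$scheme

  null_scenario <- scenario
  null_scenario$shocks <- list()
  truth <- dplyr::filter(expected_surface(null_scenario), .data$year == target_year)

  shock_years <- vapply(scenario$shocks, `[[`, integer(1), "year")
  shocked_strata <- tibble::tibble(sex = character(), age_group = character())
  shocked_strata <- unique(dplyr::bind_rows(shocked_strata, lapply(
    scenario$shocks[shock_years == target_year],
    function(s) {
      tidyr::expand_grid(
        sex = s$sexes,
        age_group = age_groups_in_range(scheme, s$age_lower, s$age_upper)
      )
    }
  )))
  # true excess per sex inside the aggregation range: shocked minus no-shock
  # expectation at the target year (exact for any mix of shock kinds)
  shocked_surface <- dplyr::filter(
    expected_surface(scenario), .data$year == target_year
  )
  surf_diff <- dplyr::mutate(shocked_surface,
    diff = .data$expected - truth$expected[match(
      paste(shocked_surface$sex, shocked_surface$age_group),
      paste(truth$sex, truth$age_group)
    )]
  )
  true_by_sex <- dplyr::summarise(
    dplyr::group_by(
      filter_age_range(surf_diff, age_range[1], age_range[2], scheme),
      .data$sex
    ),
    true_shock = sum(.data$diff), .groups = "drop"
  )

  envelope_row <- function(env) {
    dplyr::mutate(
      dplyr::select(env, "country", "sex", "age_group", "point", "lo", "hi"),
      model = "envelope"
    )
  }

  reps <- lapply(seq_len(replicates), function(r) {
    reg <- sample_registry(scenario, seed = scenario$seed + seed + r)
    withr::with_seed(seed * 1000L + r, {
      est <- fit_all(reg, scenario$country,
        target_year = target_year,
        reference_years = ref_years, models = models, scheme = scheme,
        pi_draws = pi_draws, seed = NULL
      )
      env <- combine_envelope(est)
      obs <- dplyr::filter(reg, .data$year == target_year)
      all_est <- dplyr::bind_rows(
        dplyr::select(est, "country", "sex", "age_group", "model", "point", "lo", "hi"),
        envelope_row(env)
      )
      joined <- dplyr::left_join(
        all_est,
        dplyr::select(obs, "sex", "age_group", observed = "deaths"),
        by = c("sex", "age_group")
      )
      joined <- dplyr::left_join(
        joined,
        dplyr::select(truth, "sex", "age_group", true_expected = "expected"),
        by = c("sex", "age_group")
      )
      joined$shocked <- paste(joined$sex, joined$age_group) %in%
        paste(shocked_strata$sex, shocked_strata$age_group)
      joined$covered <- joined$observed >= joined$lo & joined$observed <= joined$hi
      joined$bias <- joined$point - joined$true_expected

      exc <- compute_excess(obs, env)
      agg <- aggregate_excess(exc, by = "sex", age_range = age_range, scheme = scheme)
      list(cells = joined, agg = agg, rep = r)
    })
  })

  cells <- dplyr::bind_rows(lapply(reps, `[[`, "cells"))
  clean <- dplyr::filter(cells, !.data$shocked)
  coverage <- dplyr::summarise(
    dplyr::group_by(clean, .data$model),
    coverage = mean(.data$covered),
    mean_bias = mean(.data$bias),
    n = dplyr::n(),
    .groups = "drop"
  )
  aggs <- dplyr::bind_rows(lapply(reps, `[[`, "agg"), .id = "rep")
  excess_summary <- dplyr::summarise(
    dplyr::group_by(aggs, .data$sex),
    mean_excess = mean(.data$excess),
    se_excess = stats::sd(.data$excess) / sqrt(dplyr::n()),
    cover0 = mean(.data$lo <= 0 & .data$hi >= 0),
    .groups = "drop"
  )
  excess_summary <- dplyr::left_join(excess_summary, true_by_sex, by = "sex")
  structure(
    list(coverage = coverage, excess = excess_summary, replicates = replicates),
    class = "calibration_study"
  )
}

#' @export
print.calibration_study <- function(x, ...) {
  cat("<calibration_study>", x$replicates, "replicates\n\ncoverage (non-shocked strata):\n")
  print(x$coverage)
  cat("\naggregated excess by sex:\n")
  print(x$excess)
  invisible(x)
}
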