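#' Combine three model forecasts into the conservative envelope
#'
#' For each stratum, the final expected-death estimate is the *enveloping
#' interval* of the three models: the highest point estimate, the lowest
#' lower bound and the highest upper bound. Taking the highest expected
#' point makes the implied excess the lowest of the three, minimising
#' false-positive excess. `argmax_model` records which model supplied the
#' point; ties are broken by the fixed order OPM < OPT < LC.
#'
#' @param estimates A tibble of expected estimates (from [fit_all()]) with
#'   columns `country`, `sex`, `age_group`, `model`, `point`, `lo`, `hi`,
#'   `level`. Each stratum must carry exactly one row per model OPM, OPT,
#'   LC at a common level.
#' @return A tibble with one row per stratum: key columns plus `point`,
#'   `lo`, `hi`, `argmax_model`, `level`.
#' @export
combine_envelope <- function(estimates) {
  needed <- c("country", "sex", "age_group", "model", "point", "lo", "hi", "level")
  stopifnot(all(needed %in% names(estimates)))
  model_order <- c("OPM", "OPT", "LC")

  check <- dplyr::summarise(
    dplyr::group_by(estimates, .data$country, .data$sex, .data$age_group),
    ok = identical(sort(.data$model), sort(model_order)),
    one_level = dplyr::n_distinct(.data$level) == 1,
    .groups = "drop"
  )
  bad <- dplyr::filter(check, !.data$ok)
  if (nrow(bad)) {
    stop("stratum (", bad$country[1], ", ", bad$sex[1], ", ", bad$age_group[1],
      ") must have exactly one estimate per model OPM, OPT, LC",
      call. = FALSE
    )
  }
  if (any(!check$one_level)) stop("estimates mix interval levels", call. = FALSE)

  dplyr::summarise(
    dplyr::group_by(estimates, .data$country, .data$sex, .data$age_group),
    argmax_model = .data$model[order(
      -.data$point, match(.data$model, model_order)
    )][1],
    point = max(.data$point),
    lo = min(.data$lo),
    hi = max(.data$hi),
    level = .data$level[1],
    .groups = "drop"
  )
}

#' Excess deaths: observed minus the envelope forecast
#'
#' Excess = observed - expected point; the excess bounds come from
#' subtracting the expected interval limits from the observed count
#' (`lo = observed - hi_expected`, `hi = observed - lo_expected`). Excess
#' may be negative; it is reported as-is.
#'
#' `observed` may be a single count with a one-row `envelope` (the worked
#' single-stratum form), a numeric vector aligned with the envelope rows, or
#' a death table holding the target-year counts, which is joined on the
#' stratum key.
#'
#' @param observed Observed target-year count(s): numeric, or a death table
#'   with columns `country`, `sex`, `age_group`, `deaths`.
#' @param envelope An envelope tibble from [combine_envelope()].
#' @return A tibble with key columns plus `observed`, `expected`,
#'   `expected_lo`, `expected_hi`, `excess`, `lo`, `hi`, `argmax_model`.
#' @examples
#' env <- tibble::tibble(
#'   country = "AZE", sex = "male", age_group = "20-24",
#'   point = 337, lo = 188, hi = 405, argmax_model = "OPM", level = 0.95
#' )
#' compute_excess(1240, env) # excess 903 [835, 1052]
#' @export
compute_excess <- function(observed, envelope) {
  stopifnot(all(c("point", "lo", "hi") %in% names(envelope)))
  if (is.data.frame(observed)) {
    obs <- dplyr::select(observed, "country", "sex", "age_group", observed = "deaths")
    joined <- dplyr::left_join(envelope, obs, by = c("country", "sex", "age_group"))
    if (anyNA(joined$observed)) {
      miss <- joined[is.na(joined$observed), ]
      stop("no observed count for stratum (", miss$country[1], ", ", miss$sex[1],
        ", ", miss$age_group[1], ")",
        call. = FALSE
      )
    }
    observed <- joined$observed
    envelope <- dplyr::select(joined, -"observed")
  }
  if (any(observed < 0)) stop("observed counts must be non-negative", call. = FALSE)
  if (length(observed) != nrow(envelope)) {
    stop("`observed` must match the envelope rows", call. = FALSE)
  }
  out <- envelope
  out$observed <- observed
  out <- dplyr::rename(out,
    expected = "point", expected_lo = "lo", expected_hi = "hi"
  )
  out$excess <- out$observed - out$expected
  out$lo <- out$observed - out$expected_hi
  out$hi <- out$observed - out$expected_lo
  key <- intersect(c("country", "sex", "age_group"), names(out))
  dplyr::select(
    out, dplyr::all_of(key), "observed", "expected", "expected_lo",
    "expected_hi", "excess", "lo", "hi", dplyr::any_of(c("argmax_model", "level"))
  )
}

#' Aggregate excess deaths over strata
#'
#' Sums excess points and both interval bounds over the strata in each
#' group (plain bound summation, with no correlation adjustment — the
#' convention used when country rows are added into grand totals). An
#' optional age range first restricts the strata to whole groups inside
#' `[lower, upper]`.
#'
#' @param excess A tibble from [compute_excess()] (or any keyed table with
#'   `excess`, `lo`, `hi` columns).
#' @param by Character vector of key columns to group by (default
#'   `c("country", "sex")`); use `character()` for a grand total.
#' @param age_range Optional `c(lower, upper)` in years, aligned with
#'   `scheme` boundaries.
#' @param scheme Active [age_scheme()] (needed only when `age_range` is
#'   given).
#' @return A tibble with the `by` columns plus `n_strata`, `excess`, `lo`,
#'   `hi`.
#' @export
aggregate_excess <- function(excess, by = c("country", "sex"),
                             age_range = NULL, scheme = default_age_scheme()) {
  stopifnot(all(c("excess", "lo", "hi") %in% names(excess)))
  if (!is.null(age_range)) {
    excess <- filter_age_range(excess, age_range[1], age_range[2], scheme)
  }
  if (nrow(excess) == 0) {
    stop("no strata left to aggregate",
      if (length(by)) paste0(" (grouping by ", paste(by, collapse = ", "), ")"),
      call. = FALSE
    )
  }
  missing_by <- setdiff(by, names(excess))
  if (length(missing_by)) {
    stop("grouping column(s) not present: ", paste(missing_by, collapse = ", "),
      call. = FALSE
    )
  }
  grouped <- dplyr::group_by(excess, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(
    grouped,
    n_strata = dplyr::n(),
    excess = sum(.data$excess),
    lo = sum(.data$lo),
    hi = sum(.data$hi),
    .groups = "drop"
  )
}

#' Country-by-sex excess summary table
#'
#' Lays out aggregated excess as one row per country plus a Total row, with
#' Female, Male and Total columns, each cell formatted
#' `"point [lo, hi]"`. Values are kept at full precision internally and
#' rounded to whole deaths only at formatting time.
#'
#' @inheritParams aggregate_excess
#' @return A tibble with columns `country`, `female`, `male`, `total`.
#' @export
table1_report <- function(excess, age_range = c(15, 49),
                          scheme = default_age_scheme()) {
  by_cs <- aggregate_excess(excess,
    by = c("country", "sex"),
    age_range = age_range, scheme = scheme
  )
  fmt <- function(point, lo, hi) {
    sprintf("%d [%d, %d]", round(point), round(lo), round(hi))
  }
  wide <- tidyr::pivot_wider(
    dplyr::transmute(by_cs, .data$country, .data$sex,
      cell = fmt(.data$excess, .data$lo, .data$hi)
    ),
    names_from = "sex", values_from = "cell"
  )
  by_c <- aggregate_excess(excess, by = "country", age_range = age_range, scheme = scheme)
  wide$total <- fmt(by_c$excess, by_c$lo, by_c$hi)[match(wide$country, by_c$country)]

  by_s <- aggregate_excess(excess, by = "sex", age_range = age_range, scheme = scheme)
  grand <- aggregate_excess(excess, by = character(), age_range = age_range, scheme = scheme)
  total_row <- tibble::tibble(
    country = "Total",
    female = fmt(
      by_s$excess[by_s$sex == "female"], by_s$lo[by_s$sex == "female"],
      by_s$hi[by_s$sex == "female"]
    ),
    male = fmt(
      by_s$excess[by_s$sex == "male"], by_s$lo[by_s$sex == "male"],
      by_s$hi[by_s$sex == "male"]
    ),
    total = fmt(grand$excess, grand$lo, grand$hi)
  )
  dplyr::bind_rows(
    dplyr::select(wide, "country", dplyr::any_of(c("female", "male")), "total"),
    total_row
  )
}
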