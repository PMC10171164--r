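#' Read a stratified death-count table
#'
#' Reads a tidy CSV of registered death counts with columns
#' `country,sex,age_group,year,deaths` and validates it against an age-group
#' scheme. Each (country, sex, age_group) combination is one stratum; the
#' table is the collection of all stratum series.
#'
#' Validation is strict: `sex` must be `male` or `female` (aggregate "total"
#' rows are rejected to prevent double counting), deaths must be non-negative
#' integers, and age-group labels must exist in `scheme`. Errors name the
#' offending row.
#'
#' @param path Path to a CSV file.
#' @param scheme Active [age_scheme()].
#' @return A validated tibble with columns `country`, `sex`, `age_group`,
#'   `year`, `deaths`.
#' @seealso [write_death_table()], [to_matrix()]
#' @export
read_death_table <- function(path, scheme = default_age_scheme()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_death_table(tibble::as_tibble(raw), scheme)
}

#' Validate a death-count table
#'
#' @param tbl A data frame with columns `country`, `sex`, `age_group`,
#'   `year`, `deaths`.
#' @inheritParams read_death_table
#' @return The validated tibble (column-typed, invisibly usable downstream).
#' @export
validate_death_table <- function(tbl, scheme = default_age_scheme()) {
  required <- c("country", "sex", "age_group", "year", "deaths")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("death table is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  validate_age_scheme(scheme)
  tbl <- tibble::as_tibble(tbl)[required]

  bad_sex <- which(!tbl$sex %in% c("male", "female"))
  if (length(bad_sex)) {
    stop("row ", bad_sex[1], ": sex must be 'male' or 'female', got '",
      tbl$sex[bad_sex[1]], "'",
      call. = FALSE
    )
  }
  bad_age <- which(!tbl$age_group %in% scheme$label)
  if (length(bad_age)) {
    stop("row ", bad_age[1], ": unknown age group '", tbl$age_group[bad_age[1]], "'",
      call. = FALSE
    )
  }
  deaths <- tbl$deaths
  bad_deaths <- which(is.na(deaths) | deaths < 0 | deaths != round(deaths))
  if (length(bad_deaths)) {
    stop("row ", bad_deaths[1], ": deaths must be a non-negative integer, got ",
      deaths[bad_deaths[1]],
      call. = FALSE
    )
  }
  if (anyDuplicated(tbl[c("country", "sex", "age_group", "year")])) {
    dup <- anyDuplicated(tbl[c("country", "sex", "age_group", "year")])
    stop("row ", dup, ": duplicate (country, sex, age_group, year) cell", call. = FALSE)
  }
  tbl$year <- as.integer(tbl$year)
  tbl$deaths <- as.integer(round(deaths))
  tbl
}

#' Write a death-count table to CSV in canonical order
#'
#' Rows are ordered country, then sex (female before male), then age group in
#' scheme order, then year, so that write/read round-trips are byte-stable.
#'
#' @param tbl A validated death table.
#' @param path Output CSV path.
#' @inheritParams read_death_table
#' @return `path`, invisibly.
#' @export
write_death_table <- function(tbl, path, scheme = default_age_scheme()) {
  tbl <- validate_death_table(tbl, scheme)
  tbl <- dplyr::arrange(
    tbl, .data$country, .data$sex,
    match(.data$age_group, scheme$label), .data$year
  )
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population-exposure table
#'
#' Columns `country,sex,age_group,year,population`; exposures must be
#' strictly positive person-years. Required for the death-rates variant of
#' the baseline models.
#'
#' @inheritParams read_death_table
#' @return A validated tibble.
#' @export
read_exposure_table <- function(path, scheme = default_age_scheme()) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_exposure_table(raw, scheme)
}

#' @rdname read_exposure_table
#' @param tbl A data frame with a `population` column.
#' @export
validate_exposure_table <- function(tbl, scheme = default_age_scheme()) {
  required <- c("country", "sex", "age_group", "year", "population")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("exposure table is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  tbl <- tibble::as_tibble(tbl)[required]
  bad <- which(is.na(tbl$population) | tbl$population <= 0)
  if (length(bad)) {
    stop("row ", bad[1], ": population exposure must be > 0", call. = FALSE)
  }
  tbl$year <- as.integer(tbl$year)
  tbl
}

#' Assemble one country's death matrix
#'
#' Builds the rectangular strata-by-years count matrix that the Lee-Carter
#' model consumes: rows are (sex, age_group) strata in deterministic order
#' (sex-major, female first, then age ascending), columns are consecutive
#' years. Ragged year coverage is an error naming every missing cell.
#'
#' @param tbl A validated death table.
#' @param country Country code to extract.
#' @param allow_gaps Accept a non-contiguous (but still rectangular) set of
#'   years — needed when a reference year is excluded, as in the 2016-drop
#'   robustness run.
#' @inheritParams read_death_table
#' @return A `death_matrix`: a list with elements `country`, `strata`
#'   (tibble of `sex`, `age_group`), `years` and `counts` (matrix).
#' @seealso [matrix_to_table()] for the exact inverse.
#' @export
to_matrix <- function(tbl, country, scheme = default_age_scheme(),
                      allow_gaps = FALSE) {
  tbl <- validate_death_table(tbl, scheme)
  tbl <- dplyr::filter(tbl, .data$country == !!country)
  if (nrow(tbl) == 0) stop("no rows for country '", country, "'", call. = FALSE)

  years <- sort(unique(tbl$year))
  if (!allow_gaps && length(years) > 1 &&
    !identical(years, seq(min(years), max(years)))) {
    stop("years are not a contiguous range: ", paste(years, collapse = ", "),
      call. = FALSE
    )
  }
  strata <- dplyr::distinct(tbl, .data$sex, .data$age_group)
  strata <- dplyr::arrange(strata, .data$sex, match(.data$age_group, scheme$label))

  full <- tidyr::expand_grid(strata, year = years)
  joined <- dplyr::left_join(full, tbl, by = c("sex", "age_group", "year"))
  miss <- dplyr::filter(joined, is.na(.data$deaths))
  if (nrow(miss)) {
    cells <- paste0("(", miss$sex, ", ", miss$age_group, ", ", miss$year, ")")
    stop("missing cells for country '", country, "': ",
      paste(cells, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- matrix(joined$deaths,
    nrow = nrow(strata), ncol = length(years), byrow = TRUE,
    dimnames = list(paste(strata$sex, strata$age_group, sep = "."), years)
  )
  structure(
    list(country = country, strata = strata, years = years, counts = counts),
    class = "death_matrix"
  )
}

#' Flatten a death matrix back to the tidy table form
#'
#' Exact inverse of [to_matrix()]: `matrix_to_table(to_matrix(tbl, cc))`
#' recovers the country's rows value-for-value.
#'
#' @param dm A `death_matrix`.
#' @return A tidy death-count tibble.
#' @export
matrix_to_table <- function(dm) {
  stopifnot(inherits(dm, "death_matrix"))
  out <- tidyr::expand_grid(
    dplyr::mutate(dm$strata, country = dm$country),
    year = dm$years
  )
  out$deaths <- as.integer(t(dm$counts))[seq_len(nrow(out))]
  dplyr::select(
    out, "country", "sex", "age_group", "year", "deaths"
  )
}

#' @export
print.death_matrix <- function(x, ...) {
  cat(
    "<death_matrix> country:", x$country, "|", nrow(x$strata), "strata x",
    length(x$years), "years (", min(x$years), "-", max(x$years), ")\n"
  )
  invisible(x)
}
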