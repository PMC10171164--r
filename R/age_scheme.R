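#' Age-group schemes
#'
#' An age-group scheme is an ordered set of contiguous, non-overlapping age
#' groups starting at age 0, with exactly one open-ended terminal group. It is
#' represented as a tibble with columns `label`, `lower` and `upper` (`upper`
#' is `Inf` for the terminal group). All stratified operations in the package
#' validate age-group labels against the active scheme.
#'
#' @param lower Integer vector of lower bounds, starting at 0, strictly
#'   increasing. The last value opens the terminal group.
#' @param labels Optional character labels, one per group. Defaults to
#'   `"l-u"` for closed groups, a bare `"l"` for single-year groups and
#'   `"l+"` for the terminal group.
#' @return A tibble of class `age_scheme` with columns `label`, `lower`,
#'   `upper`.
#' @examples
#' age_scheme(c(0, 15, 65))
#' default_age_scheme()
#' @export
age_scheme <- function(lower, labels = NULL) {
  if (!is.numeric(lower) || length(lower) < 1) {
    stop("`lower` must be a non-empty numeric vector of lower bounds", call. = FALSE)
  }
  lower <- as.integer(lower)
  if (lower[1] != 0L) {
    stop("first age-group lower bound must be 0", call. = FALSE)
  }
  if (is.unsorted(lower, strictly = TRUE)) {
    stop("age-group lower bounds must be strictly increasing", call. = FALSE)
  }
  upper <- c(lower[-1] - 1L, Inf)
  if (is.null(labels)) {
    labels <- ifelse(
      is.infinite(upper), paste0(lower, "+"),
      ifelse(upper == lower, as.character(lower), paste0(lower, "-", upper))
    )
  }
  if (length(labels) != length(lower) || anyDuplicated(labels)) {
    stop("`labels` must be unique and match `lower` in length", call. = FALSE)
  }
  out <- tibble::tibble(label = as.character(labels), lower = lower, upper = upper)
  class(out) <- c("age_scheme", class(out))
  out
}

#' @describeIn age_scheme The default 16-group scheme: 0, 1-4, then 5-year
#'   groups 5-9 through 65-69, and a terminal 70+ group.
#' @export
default_age_scheme <- function() {
  age_scheme(c(0L, 1L, seq(5L, 70L, by = 5L)))
}

#' @describeIn age_scheme Validate that `x` is a well-formed scheme; returns
#'   `x` invisibly or throws.
#' @param x An object to validate.
#' @export
validate_age_scheme <- function(x) {
  if (!all(c("label", "lower", "upper") %in% names(x))) {
    stop("an age scheme needs columns label, lower, upper", call. = FALSE)
  }
  if (x$lower[1] != 0) stop("age scheme must start at age 0", call. = FALSE)
  if (sum(is.infinite(x$upper)) != 1 || !is.infinite(x$upper[nrow(x)])) {
    stop("age scheme must have exactly one open-ended terminal group", call. = FALSE)
  }
  closed <- utils::head(x, -1)
  if (nrow(x) > 1 && !all(x$lower[-1] == closed$upper + 1)) {
    stop("age groups must be contiguous and non-overlapping", call. = FALSE)
  }
  if (any(x$upper < x$lower)) stop("age-group upper < lower", call. = FALSE)
  invisible(x)
}

#' Age-group labels wholly inside an age range
#'
#' Returns the labels of the scheme's groups that lie entirely within
#' `[lower, upper]`. Bounds that would split a group are an error: counts are
#' never pro-rated across group boundaries.
#'
#' @param scheme An [age_scheme()].
#' @param lower,upper Age bounds in years (`upper = Inf` to include the
#'   terminal group).
#' @return Character vector of labels, in scheme order.
#' @export
age_groups_in_range <- function(scheme, lower, upper) {
  validate_age_scheme(scheme)
  if (!any(scheme$lower == lower)) {
    stop("lower bound ", lower, " does not align with a group boundary", call. = FALSE)
  }
  if (!any(scheme$upper == upper)) {
    stop(
      "upper bound ", upper, " splits age group '",
      scheme$label[which(scheme$lower <= upper & scheme$upper >= upper)[1]],
      "'; bounds must align with group boundaries",
      call. = FALSE
    )
  }
  scheme$label[scheme$lower >= lower & scheme$upper <= upper]
}

#' Restrict a stratified table to an age range
#'
#' Keeps exactly the rows whose `age_group` lies wholly inside
#' `[lower, upper]` under `scheme`. Works on any keyed table (death counts,
#' expected estimates, excess estimates) that carries an `age_group` column.
#'
#' @param tbl A tibble with an `age_group` column.
#' @inheritParams age_groups_in_range
#' @return The filtered tibble.
#' @examples
#' reg <- sample_registry(karabakh_preset())
#' filter_age_range(reg, 15, 49)
#' @export
filter_age_range <- function(tbl, lower, upper, scheme = default_age_scheme()) {
  stopifnot("age_group" %in% names(tbl))
  keep <- age_groups_in_range(scheme, lower, upper)
  unknown <- setdiff(unique(tbl$age_group), scheme$label)
  if (length(unknown)) {
    stop("age groups not in scheme: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  dplyr::filter(tbl, .data$age_group %in% keep)
}
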