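#' Over-dispersion (quasi-Poisson) estimate from Pearson residuals
#'
#' phi is the Pearson statistic divided by the residual degrees of freedom,
#' floored at 1 so that apparent under-dispersion never narrows predictive
#' intervals. All-zero series return phi = 1 by convention.
#'
#' @param counts Integer vector of observed counts.
#' @param fitted Numeric vector of fitted means (same length, > 0 unless all
#'   counts are zero).
#' @param n_params Number of mean-model parameters (1 for a mean, 2 for a
#'   trend).
#' @return A list with `phi` (>= 1) and `df` (residual degrees of freedom).
#' @examples
#' estimate_dispersion(c(5, 15, 5, 15, 10), rep(10, 5)) # phi = 2.5
#' @export
estimate_dispersion <- function(counts, fitted, n_params = 1L) {
  n <- length(counts)
  if (n < 2) stop("need at least 2 reference years to estimate dispersion", call. = FALSE)
  if (length(fitted) != n) stop("`fitted` must match `counts` in length", call. = FALSE)
  df <- n - n_params
  if (df < 1) {
    stop("fewer reference years than model parameters + 1", call. = FALSE)
  }
  if (all(counts == 0)) {
    return(list(phi = 1, df = df))
  }
  if (any(fitted <= 0)) stop("fitted means must be positive", call. = FALSE)
  pearson <- sum((counts - fitted)^2 / fitted)
  list(phi = max(1, pearson / df), df = df)
}

# Negative-binomial draw parameterised by mean and variance-to-mean ratio phi
# (variance = phi * mu); phi = 1 is exact Poisson. Vectorised over mu.
# Means are capped below the integer-RNG ceiling: draws near-degenerate fits
# can send exp(eta) to infinity, where rpois/rnbinom return NA.
rcount_overdispersed <- function(n, mu, phi) {
  mu <- pmin(rep_len(mu, n), 1e8)
  if (phi <= 1 + 1e-12) {
    return(stats::rpois(n, mu))
  }
  out <- integer(n)
  pos <- mu > 0
  # var = mu + mu^2/size = phi*mu  =>  size = mu / (phi - 1)
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / (phi - 1))
  out
}

# Draws from the predictive distribution of one future count given a
# log-scale linear predictor with estimated mean/sd and dispersion phi.
# The linear predictor is drawn from a t with `df` degrees of freedom
# (plug-in dispersion is noisy at 4-5 reference years; the t draw is the
# small-sample analogue of the asymptotic normal), then the count from the
# matching over-dispersed distribution.
predictive_draws <- function(eta_mean, eta_sd, phi, draws, df = Inf) {
  scale_draw <- if (is.finite(df)) stats::rt(draws, df = df) else stats::rnorm(draws)
  mu <- exp(eta_mean + eta_sd * scale_draw)
  rcount_overdispersed(draws, mu, phi)
}

predictive_interval <- function(y, level) {
  alpha <- (1 - level) / 2
  q <- stats::quantile(y, c(alpha, 1 - alpha), names = FALSE, type = 8)
  c(lo = max(0, q[1]), hi = q[2])
}

new_expected_estimate <- function(model, point, lo, hi, level, phi) {
  tibble::tibble(
    model = model, point = point, lo = lo, hi = hi, level = level, phi = phi
  )
}

#' Over-dispersed Poisson mean (OPM) forecast
#'
#' The point forecast for the target year is the arithmetic mean of the
#' reference-window counts. The predictive interval is for a single future
#' count: the log-mean is drawn from its estimated sampling distribution and
#' a count is drawn from an over-dispersed (negative-binomial) distribution
#' with variance phi times the mean; the interval is the empirical
#' 2.5/97.5 percentile band (at `level = 0.95`) of `pi_draws` such draws.
#'
#' @param counts Integer vector of reference-year death counts (>= 2 years).
#' @param target_year Year being forecast (recorded, not used by the mean
#'   model).
#' @param years Optional integer vector of reference years (for records).
#' @param level Predictive-interval level, default 0.95.
#' @param pi_draws Number of simulation draws for the interval.
#' @param seed Optional integer seed applied locally to the interval
#'   simulation.
#' @return A one-row tibble: `model`, `point`, `lo`, `hi`, `level`, `phi`.
#' @examples
#' fit_opm(c(12, 9, 11, 10, 8), target_year = 2020, seed = 1)
#' @export
fit_opm <- function(counts, target_year = NULL, years = NULL, level = 0.95,
                    pi_draws = 1e5, seed = NULL) {
  if (length(counts) < 2) stop("OPM needs at least 2 reference years", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mu <- mean(counts)
  if (mu == 0) {
    return(new_expected_estimate("OPM", 0, 0, 0, level, 1))
  }
  disp <- estimate_dispersion(counts, rep(mu, length(counts)), n_params = 1L)
  # log-link intercept-only quasi-Poisson: Var(eta_hat) = phi / (n * mu)
  eta_sd <- sqrt(disp$phi / (length(counts) * mu))
  sim <- function() {
    predictive_draws(log(mu), eta_sd, disp$phi, pi_draws, df = disp$df)
  }
  y <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  q <- predictive_interval(y, level)
  new_expected_estimate("OPM", mu, q[["lo"]], q[["hi"]], level, disp$phi)
}

#' Over-dispersed Poisson trend (OPT) forecast
#'
#' Fits a year trend by Poisson regression (log link by default, so the
#' trend is log-linear and forecasts stay non-negative; `link = "identity"`
#' gives a straight-line trend for sensitivity checks) and extrapolates to
#' the target year. Dispersion is estimated from Pearson residuals, floored
#' at 1, and the predictive interval is simulated as in [fit_opm()] with the
#' extra slope uncertainty included through the linear predictor's standard
#' error at the target year.
#'
#' @inheritParams fit_opm
#' @param years Integer vector of reference years, same length as `counts`.
#' @param link `"log"` (default) or `"identity"`.
#' @param offset Optional log-exposure offset per reference year, with
#'   `offset_target` its value at the target year (rates variant).
#' @param offset_target Log exposure at the target year.
#' @return A one-row tibble as in [fit_opm()].
#' @export
fit_opt <- function(counts, years, target_year, level = 0.95,
                    link = c("log", "identity"), pi_draws = 1e5, seed = NULL,
                    offset = NULL, offset_target = 0) {
  link <- match.arg(link)
  if (length(counts) < 3) {
    stop("OPT needs at least 3 reference years (slope unidentifiable with dispersion)",
      call. = FALSE
    )
  }
  if (length(years) != length(counts)) stop("`years` must match `counts`", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) {
    return(new_expected_estimate("OPT", 0, 0, 0, level, 1))
  }
  yr_c <- years - mean(years)
  target_c <- target_year - mean(years)
  off <- if (is.null(offset)) rep(0, length(counts)) else offset

  if (link == "log") {
    fit <- suppressWarnings(
      stats::glm(counts ~ yr_c, family = stats::poisson(), offset = off)
    )
    # predict() re-evaluates the `off` offset symbol in newdata
    pred <- stats::predict(fit,
      newdata = data.frame(yr_c = target_c, off = offset_target),
      type = "link", se.fit = TRUE
    )
    eta <- unname(pred$fit)
    se1 <- unname(pred$se.fit) # at dispersion 1
    disp <- estimate_dispersion(counts, stats::fitted(fit), n_params = 2L)
    eta_sd <- se1 * sqrt(disp$phi)
    point <- exp(eta)
    sim <- function() predictive_draws(eta, eta_sd, disp$phi, pi_draws, df = disp$df)
    y <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
    q <- predictive_interval(y, level)
    return(new_expected_estimate("OPT", point, q[["lo"]], q[["hi"]], level, disp$phi))
  }

  # identity link: straight-line trend on the count scale, started from lm
  start <- stats::coef(stats::lm(counts ~ yr_c))
  fit <- suppressWarnings(stats::glm(counts ~ yr_c,
    family = stats::poisson(link = "identity"), start = start
  ))
  pred <- stats::predict(fit,
    newdata = data.frame(yr_c = target_c),
    type = "response", se.fit = TRUE
  )
  mu_hat <- max(unname(pred$fit), 1e-8) * exp(offset_target)
  se1 <- unname(pred$se.fit) * exp(offset_target)
  disp <- estimate_dispersion(counts, pmax(stats::fitted(fit), 1e-8), n_params = 2L)
  sd_mu <- se1 * sqrt(disp$phi)
  sim <- function() {
    scale_draw <- stats::rt(pi_draws, df = disp$df)
    mu <- pmax(mu_hat + sd_mu * scale_draw, 0)
    rcount_overdispersed(pi_draws, mu, disp$phi)
  }
  y <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  q <- predictive_interval(y, level)
  new_expected_estimate("OPT", mu_hat, q[["lo"]], q[["hi"]], level, disp$phi)
}

#' Lee-Carter forecast on death counts
#'
#' Decomposes the log count surface of one country's full age-sex-year
#' matrix as `log d[i, t] = alpha_i + beta_i * kappa_t` (first singular pair
#' of the row-centred log matrix, with the usual constraints sum(beta) = 1,
#' sum(kappa) = 0) and forecasts kappa to the target year by a random walk
#' with drift (drift = mean first difference; innovation variance = sample
#' variance of first differences). The per-stratum predictive interval
#' combines drift uncertainty, innovation variance and over-dispersed count
#' noise with a single dispersion factor shared across the matrix.
#'
#' Zero cells are replaced by `zero_offset` (default 0.5) before taking
#' logs, with a warning; small-population registries routinely contain
#' zeros and the SVD needs finite logs.
#'
#' @param dm A `death_matrix` from [to_matrix()] (>= 3 years, >= 2 strata).
#' @param target_year Year to forecast.
#' @param level Predictive-interval level.
#' @param pi_draws Simulation draws per stratum.
#' @param seed Optional local seed.
#' @param zero_offset Replacement value for zero cells before logging.
#' @param exposure Optional exposure matrix (same shape as `dm$counts` plus
#'   a target-year column attribute) for the rates variant; see
#'   [fit_all()].
#' @return A tibble with one row per stratum: `sex`, `age_group`, `model`
#'   (`"LC"`), `point`, `lo`, `hi`, `level`, `phi`, plus the drift as an
#'   attribute `kappa_drift`.
#' @export
fit_lee_carter <- function(dm, target_year, level = 0.95, pi_draws = 1e5,
                           seed = NULL, zero_offset = 0.5, exposure = NULL) {
  stopifnot(inherits(dm, "death_matrix"))
  d <- dm$counts
  n_strata <- nrow(d)
  n_years <- ncol(d)
  if (n_years < 3) stop("Lee-Carter needs at least 3 years", call. = FALSE)
  if (n_strata < 2) stop("Lee-Carter needs at least 2 strata", call. = FALSE)
  if (any(d < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(zero_offset) && any(d == 0)) {
    stop("matrix contains zero counts and zero-handling is disabled", call. = FALSE)
  }

  work <- d
  if (!is.null(exposure)) {
    e_ref <- exposure$reference
    stopifnot(all(dim(e_ref) == dim(d)), all(e_ref > 0))
    work <- d / e_ref
  }
  if (any(work == 0)) {
    warning(sum(work == 0), " zero cell(s) replaced by ", zero_offset,
      " before taking logs",
      call. = FALSE
    )
    work[work == 0] <- zero_offset * if (is.null(exposure)) 1 else 1 / mean(exposure$reference)
  }
  L <- log(work)

  alpha <- rowMeans(L)
  Z <- L - alpha
  sv <- svd(Z)
  u1 <- sv$u[, 1]
  v1 <- sv$v[, 1]
  d1 <- sv$d[1]
  if (sum(u1) < 0) {
    u1 <- -u1
    v1 <- -v1
  }
  s <- sum(u1)
  if (abs(s) < 1e-10) {
    stop("degenerate age pattern: sum of leading singular vector is ~0", call. = FALSE)
  }
  beta <- u1 / s
  kappa <- d1 * s * v1
  # re-centre kappa (row-centring does not force column means to zero)
  m <- mean(kappa)
  kappa <- kappa - m
  alpha <- alpha + beta * m

  # random walk with drift on kappa; year gaps (an excluded reference year)
  # are handled by weighting increments with their spacing
  dk <- diff(kappa)
  dt <- diff(dm$years)
  drift <- sum(dk) / sum(dt)
  m <- length(dk)
  sig2 <- if (m > 1) sum((dk - drift * dt)^2 / dt) / (m - 1) else 0
  if (is.na(sig2)) sig2 <- 0
  h <- target_year - max(dm$years)
  if (h <= 0) stop("target year must follow the reference window", call. = FALSE)
  kappa_T <- kappa[n_years]
  kappa_fc <- kappa_T + h * drift
  # forecast variance: h years of innovation + drift-estimation uncertainty
  var_fc <- h * sig2 + (h^2) * sig2 / sum(dt)
  df_k <- max(m - 1, 1)

  mu_point <- exp(alpha + beta * kappa_fc)
  fitted_mu <- exp(alpha + outer(beta, kappa))
  if (!is.null(exposure)) {
    fitted_mu <- fitted_mu * exposure$reference
    mu_point <- mu_point * exposure$target
  }
  n_par <- 2 * n_strata + n_years - 2
  df_phi <- max(n_strata * n_years - n_par, 1)
  pearson <- sum((d - fitted_mu)^2 / pmax(fitted_mu, 1e-8))
  phi <- max(1, pearson / df_phi)

  sim <- function() {
    k_draw <- kappa_fc + sqrt(var_fc) * stats::rt(pi_draws, df = df_k)
    vapply(seq_len(n_strata), function(i) {
      mu_i <- exp(alpha[i] + beta[i] * k_draw)
      if (!is.null(exposure)) mu_i <- mu_i * exposure$target[i]
      predictive_interval(rcount_overdispersed(pi_draws, mu_i, phi), level)
    }, numeric(2))
  }
  qs <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())

  out <- tibble::tibble(
    sex = dm$strata$sex,
    age_group = dm$strata$age_group,
    model = "LC",
    point = unname(mu_point),
    lo = qs[1, ],
    hi = qs[2, ],
    level = level,
    phi = phi
  )
  attr(out, "kappa_drift") <- drift
  attr(out, "kappa") <- kappa
  out
}

#' Fit all three baseline models for one country
#'
#' Runs the over-dispersed Poisson mean (OPM), over-dispersed Poisson trend
#' (OPT) and count Lee-Carter (LC) models on every stratum of one country
#' and returns exactly three expected-death estimates per stratum. In
#' `mode = "rates"` the OPM/OPT fits use a log-exposure offset and the LC
#' fit runs on death rates, with all results returned on the deaths scale
#' (an exposure table covering the reference years and the target year is
#' then required).
#'
#' @param tbl A validated death table containing the country's reference
#'   years and (optionally) the target year.
#' @param country Country code.
#' @param target_year Forecast year (default 2020).
#' @param reference_years Reference window (default 2015:2019).
#' @param exclude_years Years dropped from the reference window, e.g.
#'   `2016` for the conflict-flare robustness run.
#' @param models Subset of `c("OPM", "OPT", "LC")`.
#' @param mode `"counts"` (default) or `"rates"`.
#' @param exposure Exposure tibble (see [read_exposure_table()]), required
#'   in rates mode.
#' @param scheme Active [age_scheme()].
#' @param level,pi_draws Interval level and simulation draws.
#' @param seed Integer seed for the interval simulations (applied once).
#' @param opt_link Link for the OPT trend, `"log"` or `"identity"`.
#' @return A tibble with one row per stratum x model: `country`, `sex`,
#'   `age_group`, `model`, `point`, `lo`, `hi`, `level`, `phi`.
#' @examples
#' reg <- sample_registry(karabakh_preset())
#' est <- fit_all(reg, "ARM", pi_draws = 2000, seed = 7)
#' @export
fit_all <- function(tbl, country, target_year = 2020L,
                    reference_years = 2015:2019, exclude_years = integer(),
                    models = c("OPM", "OPT", "LC"), mode = c("counts", "rates"),
                    exposure = NULL, scheme = default_age_scheme(),
                    level = 0.95, pi_draws = 1e5, seed = 20201127,
                    opt_link = "log") {
  mode <- match.arg(mode)
  models <- match.arg(models, c("OPM", "OPT", "LC"), several.ok = TRUE)
  ref <- setdiff(reference_years, exclude_years)
  if (target_year %in% ref) stop("target year cannot be a reference year", call. = FALSE)
  tbl <- validate_death_table(tbl, scheme)
  ref_tbl <- dplyr::filter(tbl, .data$country == !!country, .data$year %in% ref)
  if (nrow(ref_tbl) == 0) stop("no reference-year rows for '", country, "'", call. = FALSE)

  exp_tbl <- NULL
  if (mode == "rates") {
    if (is.null(exposure)) stop("rates mode requires an exposure table", call. = FALSE)
    exp_tbl <- validate_exposure_table(exposure, scheme)
    exp_tbl <- dplyr::filter(exp_tbl, .data$country == !!country)
  }

  if (!is.null(seed)) {
    return(withr::with_seed(seed, fit_all(tbl, country,
      target_year = target_year,
      reference_years = reference_years, exclude_years = exclude_years,
      models = models, mode = mode, exposure = exposure, scheme = scheme,
      level = level, pi_draws = pi_draws, seed = NULL, opt_link = opt_link
    )))
  }

  strata <- dplyr::distinct(ref_tbl, .data$sex, .data$age_group)
  strata <- dplyr::arrange(strata, .data$sex, match(.data$age_group, scheme$label))

  lookup_exposure <- function(sex, age_group, yrs) {
    e <- exp_tbl[exp_tbl$sex == sex & exp_tbl$age_group == age_group, ]
    out <- e$population[match(yrs, e$year)]
    if (anyNA(out)) {
      stop("missing exposure for (", sex, ", ", age_group, ") in year(s) ",
        paste(yrs[is.na(out)], collapse = ", "),
        call. = FALSE
      )
    }
    out
  }

  per_stratum <- lapply(seq_len(nrow(strata)), function(i) {
    s <- strata$sex[i]
    a <- strata$age_group[i]
    sub <- dplyr::filter(ref_tbl, .data$sex == s, .data$age_group == a)
    sub <- dplyr::arrange(sub, .data$year)
    rows <- list()
    off <- NULL
    off_t <- 0
    if (mode == "rates") {
      off <- log(lookup_exposure(s, a, sub$year))
      off_t <- log(lookup_exposure(s, a, target_year))
    }
    if ("OPM" %in% models) {
      est <- tryCatch(
        {
          if (mode == "rates") {
            fit_opm_offset(sub$deaths, off, off_t, level = level, pi_draws = pi_draws)
          } else {
            fit_opm(sub$deaths,
              target_year = target_year, years = sub$year,
              level = level, pi_draws = pi_draws
            )
          }
        },
        error = function(e) stop("OPM (", s, ", ", a, "): ", conditionMessage(e), call. = FALSE)
      )
      rows <- c(rows, list(est))
    }
    if ("OPT" %in% models) {
      est <- tryCatch(
        fit_opt(sub$deaths, sub$year, target_year,
          level = level, link = opt_link,
          pi_draws = pi_draws, offset = off, offset_target = off_t
        ),
        error = function(e) stop("OPT (", s, ", ", a, "): ", conditionMessage(e), call. = FALSE)
      )
      rows <- c(rows, list(est))
    }
    dplyr::bind_cols(
      tibble::tibble(country = country, sex = s, age_group = a),
      dplyr::bind_rows(rows)
    )
  })
  out <- dplyr::bind_rows(per_stratum)

  if ("LC" %in% models) {
    dm <- to_matrix(ref_tbl, country, scheme, allow_gaps = TRUE)
    lc_exposure <- NULL
    if (mode == "rates") {
      e_ref <- t(vapply(
        seq_len(nrow(dm$strata)),
        function(i) lookup_exposure(dm$strata$sex[i], dm$strata$age_group[i], dm$years),
        numeric(length(dm$years))
      ))
      e_tgt <- vapply(
        seq_len(nrow(dm$strata)),
        function(i) lookup_exposure(dm$strata$sex[i], dm$strata$age_group[i], target_year),
        numeric(1)
      )
      lc_exposure <- list(reference = e_ref, target = e_tgt)
    }
    lc <- fit_lee_carter(dm, target_year,
      level = level, pi_draws = pi_draws,
      exposure = lc_exposure
    )
    lc <- dplyr::mutate(lc, country = country, .before = 1)
    out <- dplyr::bind_rows(out, lc)
  }
  dplyr::arrange(
    out, .data$sex, match(.data$age_group, scheme$label),
    match(.data$model, c("OPM", "OPT", "LC"))
  )
}

# OPM with a log-exposure offset (rates variant): the fitted rate is
# sum(d) / sum(E); the point forecast is rate * E_target.
fit_opm_offset <- function(counts, log_exposure, log_exposure_target,
                           level = 0.95, pi_draws = 1e5) {
  if (length(counts) < 2) stop("OPM needs at least 2 reference years", call. = FALSE)
  E <- exp(log_exposure)
  E_t <- exp(log_exposure_target)
  if (all(counts == 0)) {
    return(new_expected_estimate("OPM", 0, 0, 0, level, 1))
  }
  rate <- sum(counts) / sum(E)
  mu_ref <- rate * E
  disp <- estimate_dispersion(counts, mu_ref, n_params = 1L)
  eta <- log(rate * E_t)
  eta_sd <- sqrt(disp$phi / sum(mu_ref))
  y <- predictive_draws(eta, eta_sd, disp$phi, pi_draws, df = disp$df)
  q <- predictive_interval(y, level)
  new_expected_estimate("OPM", rate * E_t, q[["lo"]], q[["hi"]], level, disp$phi)
}
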