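# independent Monte-Carlo oracle for the predictive distribution of one
# future count: t-draw on the log mean, then a negative-binomial count with
# variance phi * mean (written out here without the package's helpers)
oracle_predictive_quantiles <- function(mu, eta_sd, phi, df, level = 0.95,
                                        draws = 2e5) {
  eta <- log(mu) + eta_sd * stats::rt(draws, df = df)
  m <- exp(eta)
  y <- if (phi <= 1) {
    stats::rpois(draws, m)
  } else {
    stats::rnbinom(draws, mu = m, size = m / (phi - 1))
  }
  alpha <- (1 - level) / 2
  stats::quantile(y, c(alpha, 1 - alpha), names = FALSE, type = 8)
}

test_that("dispersion is Pearson/df floored at one", {
  expect_equal(estimate_dispersion(rep(10L, 5), rep(10, 5))$phi, 1)
  d <- estimate_dispersion(c(5L, 15L, 5L, 15L, 10L), rep(10, 5))
  expect_equal(d$phi, 2.5)
  expect_equal(d$df, 4)
  expect_equal(estimate_dispersion(c(0L, 0L, 0L), rep(0, 3))$phi, 1)
  expect_error(estimate_dispersion(c(1L, 2L), rep(1.5, 2), n_params = 2L), "fewer reference years")
})

test_that("OPM point is exactly the reference-window mean", {
  expect_equal(fit_opm(rep(10L, 5), pi_draws = 500, seed = 1)$point, 10)
  expect_equal(fit_opm(c(12L, 9L, 11L, 10L, 8L), pi_draws = 500, seed = 1)$point, 10)
  for (i in 1:10) {
    counts <- rpois(5, lambda = 10^runif(1, 0, 3))
    expect_identical(fit_opm(counts, pi_draws = 200, seed = i)$point, mean(counts))
  }
  z <- fit_opm(rep(0L, 5), seed = 1)
  expect_equal(c(z$point, z$lo, z$hi), c(0, 0, 0))
})

test_that("OPM interval matches an independent Monte-Carlo oracle", {
  counts <- c(12L, 9L, 11L, 10L, 8L)
  fit <- fit_opm(counts, pi_draws = 5e5, seed = 42)
  mu <- mean(counts)
  phi <- max(1, sum((counts - mu)^2 / mu) / 4)
  set.seed(99)
  q <- oracle_predictive_quantiles(mu, sqrt(phi / (5 * mu)), phi, df = 4, draws = 5e5)
  # counts are discrete: the interpolated tail quantiles can disagree by up
  # to about one death under independent draws
  expect_lt(abs(fit$lo - max(0, q[1])), 1.0)
  expect_lt(abs(fit$hi - q[2]), 1.0)
})

test_that("OPT continues a noiseless log-linear trend exactly", {
  counts <- c(10L, 20L, 40L, 80L, 160L) # doubling per year
  fit <- fit_opt(counts, 2015:2019, 2020, pi_draws = 500, seed = 1)
  expect_equal(fit$point, 320, tolerance = 1e-6)
  # three-year window and a different ratio
  fit2 <- fit_opt(c(9L, 27L, 81L), 2017:2019, 2021, pi_draws = 500, seed = 1)
  expect_equal(fit2$point, 729, tolerance = 1e-6)
})

test_that("OPT on constant counts has zero slope and is at least as wide as OPM", {
  counts <- rep(10L, 5)
  opm <- fit_opm(counts, pi_draws = 1e5, seed = 7)
  opt <- fit_opt(counts, 2015:2019, 2020, pi_draws = 1e5, seed = 7)
  expect_equal(opt$point, 10, tolerance = 1e-8)
  expect_gte((opt$hi - opt$lo) - (opm$hi - opm$lo), -0.5)
})

test_that("OPT point agrees with an independent likelihood-maximisation oracle", {
  counts <- c(10L, 11L, 9L, 30L, 12L) # one high outlier year
  years <- 2015:2019
  fit <- fit_opt(counts, years, 2020, pi_draws = 500, seed = 1)
  # oracle: maximise the Poisson log-likelihood directly
  x <- years - mean(years)
  nll <- function(p) -sum(stats::dpois(counts, exp(p[1] + p[2] * x), log = TRUE))
  opt <- stats::optim(c(log(mean(counts)), 0), nll, method = "BFGS")
  oracle_point <- exp(opt$par[1] + opt$par[2] * (2020 - mean(years)))
  expect_equal(fit$point, oracle_point, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(fit$point, mean(counts))))
})

test_that("identity-link OPT continues a straight-line trend", {
  counts <- c(100L, 110L, 120L, 130L, 140L)
  fit <- fit_opt(counts, 2015:2019, 2020, link = "identity", pi_draws = 500, seed = 1)
  expect_equal(fit$point, 150, tolerance = 1e-6)
})

test_that("OPT requires three reference years", {
  expect_error(fit_opt(c(5L, 6L), 2018:2019, 2020), "at least 3")
})

test_that("Lee-Carter reproduces constant and noiseless rank-1 matrices", {
  const <- matrix_fixture(matrix(7, 4, 5))
  f <- fit_lee_carter(const, 2020, pi_draws = 500, seed = 1)
  expect_equal(f$point, rep(7, 4))
  expect_equal(attr(f, "kappa_drift"), 0)

  alpha <- c(3, 4, 2.5, 5)
  beta <- c(0.4, 0.2, 0.3, 0.1)
  kappa <- seq(-2, 2)
  d <- exp(outer(alpha, rep(1, 5)) + outer(beta, kappa))
  dm <- matrix_fixture(d)
  fit <- fit_lee_carter(dm, 2020, pi_draws = 500, seed = 1)
  truth <- exp(alpha + beta * 3)
  expect_equal(fit$point, truth, tolerance = 1e-6)
})

test_that("Lee-Carter recovers the drift of a simulated parameterisation", {
  # 40 years x 16 strata, Poisson noise, linear-drift kappa
  set.seed(2024)
  n_s <- 16
  n_y <- 40
  alpha <- runif(n_s, 2, 5)
  beta <- runif(n_s)
  beta <- beta / sum(beta)
  drift_true <- 0.5
  reps <- 40
  drifts <- replicate(reps, {
    kappa <- cumsum(c(0, rnorm(n_y - 1, drift_true, 0.3)))
    kappa <- kappa - mean(kappa)
    mu <- exp(outer(alpha, rep(1, n_y)) + outer(beta, kappa))
    d <- matrix(rpois(length(mu), mu), n_s, n_y)
    dm <- matrix_fixture(d, years = 1981:2020)
    attr(
      suppressWarnings(fit_lee_carter(dm, 2021, pi_draws = 50)),
      "kappa_drift"
    ) # low-count cells may hit the zero-offset path; that warning is expected
  })
  se <- sd(drifts) / sqrt(reps)
  expect_lt(abs(mean(drifts) - drift_true), 3 * se + 0.02)
})

test_that("Lee-Carter flags degenerate input and handles zero cells", {
  one_year <- matrix_fixture(matrix(5, 4, 1), years = 2019)
  expect_error(fit_lee_carter(one_year, 2020), "at least 3 years")
  with_zero <- matrix_fixture(matrix(c(0, 3, 4, 5, 0, 4, 5, 6, 1, 3, 4, 7), 4, 3))
  expect_warning(fit_lee_carter(with_zero, 2018, pi_draws = 200, seed = 1), "zero cell")
  expect_error(
    suppressWarnings(fit_lee_carter(with_zero, 2018, zero_offset = NULL)),
    "zero-handling"
  )
})

test_that("intervals satisfy lo <= point <= hi with lo >= 0 across generated cases", {
  set.seed(11)
  for (i in 1:15) {
    counts <- rpois(5, 10^runif(1, 0, 2.5)) + rbinom(5, 20, 0.3)
    opm <- fit_opm(counts, pi_draws = 4000)
    opt <- fit_opt(counts, 2015:2019, 2020, pi_draws = 4000)
    for (f in list(opm, opt)) {
      expect_gte(f$lo, 0)
      expect_lte(f$lo, f$point + 1e-9)
      expect_gte(f$hi, f$point - max(1, 0.05 * f$point))
    }
  }
  reg <- sample_registry(calibration_scenario(), seed = 3)
  lc <- fit_lee_carter(to_matrix(dplyr::filter(reg, year < 2020), "CAL",
    calibration_scheme()
  ), 2020, pi_draws = 4000, seed = 5)
  expect_true(all(lc$lo >= 0 & lc$lo <= lc$point & lc$point <= lc$hi))
})

test_that("widening the dispersion never narrows the predictive interval", {
  widths <- vapply(c(1, 2, 4, 8), function(phi) {
    y <- withr::with_seed(123, {
      eta <- log(100) + sqrt(phi / (5 * 100)) * rt(5e4, df = 4)
      mu <- exp(eta)
      if (phi == 1) rpois(5e4, mu) else rnbinom(5e4, mu = mu, size = mu / (phi - 1))
    })
    q <- quantile(y, c(0.025, 0.975), names = FALSE, type = 8)
    q[2] - max(0, q[1])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  # and through the fitted models themselves: scale counts to raise phi
  calm <- fit_opm(c(99L, 101L, 100L, 99L, 101L), pi_draws = 5e4, seed = 5)
  noisy <- fit_opm(c(70L, 130L, 80L, 120L, 100L), pi_draws = 5e4, seed = 5)
  expect_gt(noisy$phi, calm$phi)
  expect_gt(noisy$hi - noisy$lo, calm$hi - calm$lo)
})

test_that("scaling counts by an integer scales OPM exactly and OPT to tolerance", {
  counts <- c(12L, 9L, 11L, 10L, 8L)
  k <- 7L
  expect_equal(
    fit_opm(counts * k, pi_draws = 200, seed = 1)$point,
    k * fit_opm(counts, pi_draws = 200, seed = 1)$point
  )
  expect_equal(
    fit_opt(counts * k, 2015:2019, 2020, pi_draws = 200, seed = 1)$point,
    k * fit_opt(counts, 2015:2019, 2020, pi_draws = 200, seed = 1)$point,
    tolerance = 1e-6
  )
})

test_that("fit_all returns three estimates per stratum and honours exclusions", {
  reg <- sample_registry(karabakh_preset())
  est <- fit_all(reg, "SYN", pi_draws = 1000, seed = 2)
  expect_equal(nrow(est), 32 * 3)
  counts_per_stratum <- dplyr::count(est, sex, age_group)
  expect_true(all(counts_per_stratum$n == 3))

  # excluding 2016 changes the OPM mean to the 4-year average
  sub <- dplyr::filter(reg, sex == "male", age_group == "20-24", year < 2020)
  est_ex <- fit_all(reg, "SYN",
    exclude_years = 2016, models = "OPM",
    pi_draws = 500, seed = 2
  )
  row <- dplyr::filter(est_ex, sex == "male", age_group == "20-24")
  expect_equal(row$point, mean(sub$deaths[sub$year != 2016]))
})

test_that("rates mode with constant exposure matches counts mode", {
  reg <- sample_registry(calibration_scenario(), seed = 9, exposure = TRUE)
  exposure <- attr(reg, "exposure")
  est_counts <- fit_all(reg, "CAL",
    scheme = calibration_scheme(),
    pi_draws = 2000, seed = 31
  )
  est_rates <- fit_all(reg, "CAL",
    scheme = calibration_scheme(), mode = "rates",
    exposure = exposure, pi_draws = 2000, seed = 31
  )
  expect_equal(est_rates$point, est_counts$point, tolerance = 1e-6)
})
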