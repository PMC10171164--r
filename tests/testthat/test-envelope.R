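make_estimates <- function(points, lows, highs, key = list(
                             country = "X", sex = "male", age_group = "20-24"
                           )) {
  tibble::tibble(
    country = key$country, sex = key$sex, age_group = key$age_group,
    model = c("OPM", "OPT", "LC"), point = points, lo = lows, hi = highs,
    level = 0.95, phi = 1
  )
}

test_that("envelope takes max point, min lower, max upper", {
  est <- make_estimates(c(100, 105, 98), c(90, 95, 85), c(110, 120, 108))
  env <- combine_envelope(est)
  expect_equal(env$point, 105)
  expect_equal(env$lo, 85)
  expect_equal(env$hi, 120)
  expect_equal(env$argmax_model, "OPT")
})

test_that("envelope of identical estimates is idempotent and ties break OPM < OPT < LC", {
  est <- make_estimates(c(50, 50, 50), c(40, 40, 40), c(60, 60, 60))
  env <- combine_envelope(est)
  expect_equal(c(env$point, env$lo, env$hi), c(50, 40, 60))
  expect_equal(env$argmax_model, "OPM")
  est2 <- make_estimates(c(40, 50, 50), c(30, 40, 40), c(55, 60, 60))
  expect_equal(combine_envelope(est2)$argmax_model, "OPT")
})

test_that("duplicate or missing models are rejected", {
  est <- make_estimates(c(100, 105, 98), c(90, 95, 85), c(110, 120, 108))
  expect_error(combine_envelope(est[c(1, 1, 3), ]), "exactly one estimate per model")
  expect_error(combine_envelope(est[1:2, ]), "exactly one estimate per model")
})

test_that("envelope interval contains each model interval", {
  set.seed(42)
  for (i in 1:20) {
    pts <- runif(3, 10, 200)
    los <- pts - runif(3, 1, 50)
    his <- pts + runif(3, 1, 50)
    env <- combine_envelope(make_estimates(pts, los, his))
    expect_lte(env$lo, min(los))
    expect_gte(env$hi, max(his))
    expect_equal(env$point, max(pts))
  }
})

test_that("excess subtraction reproduces the worked single-stratum examples", {
  env_aze <- tibble::tibble(
    country = "Azerbaijan", sex = "male", age_group = "20-24",
    point = 337, lo = 188, hi = 405, argmax_model = "OPM", level = 0.95
  )
  ex <- compute_excess(1240, env_aze)
  expect_equal(c(ex$excess, ex$lo, ex$hi), c(903, 835, 1052))

  env_art <- dplyr::mutate(env_aze, country = "Artsakh", point = 6, lo = 0, hi = 14)
  ex2 <- compute_excess(83, env_art)
  expect_equal(c(ex2$excess, ex2$lo, ex2$hi), c(77, 69, 83))

  # observed equal to the envelope point gives zero excess
  ex3 <- compute_excess(337, env_aze)
  expect_equal(ex3$excess, 0)
  expect_true(ex3$lo <= 0 && ex3$hi >= 0)
})

test_that("excess from a death table joins on the stratum key", {
  reg <- sample_registry(karabakh_preset())
  est <- fit_all(reg, "SYN", pi_draws = 500, seed = 3)
  env <- combine_envelope(est)
  obs <- dplyr::filter(reg, year == 2020)
  ex <- compute_excess(obs, env)
  expect_equal(nrow(ex), 32)
  expect_equal(ex$excess, ex$observed - ex$expected)
  expect_equal(ex$lo, ex$observed - ex$expected_hi)
  expect_equal(ex$hi, ex$observed - ex$expected_lo)
  expect_error(
    compute_excess(dplyr::filter(obs, sex == "male"), env),
    "no observed count"
  )
})

test_that("aggregation sums points and both bounds over included strata", {
  cells <- tibble::tibble(
    country = rep(c("A", "B"), each = 2),
    sex = rep(c("female", "male"), 2),
    age_group = "20-24",
    excess = c(10, 100, -5, 50),
    lo = c(-20, 60, -30, 10),
    hi = c(40, 150, 20, 90)
  )
  by_country <- aggregate_excess(cells, by = "country")
  expect_equal(by_country$excess, c(110, 45))
  expect_equal(by_country$lo, c(40, -20))
  expect_equal(by_country$hi, c(190, 110))
  # single-stratum group equals that stratum
  single <- aggregate_excess(cells[1, ], by = c("country", "sex"))
  expect_equal(single$excess, 10)
  expect_equal(single$n_strata, 1)
  # linearity: union of disjoint groups equals the grand total
  grand <- aggregate_excess(cells, by = character())
  expect_equal(grand$excess, sum(by_country$excess))
  expect_equal(grand$lo, sum(by_country$lo))
  expect_equal(grand$hi, sum(by_country$hi))
})

test_that("empty aggregation groups raise an error", {
  cells <- tibble::tibble(
    country = "A", sex = "male", age_group = "70+",
    excess = 1, lo = 0, hi = 2
  )
  expect_error(aggregate_excess(cells, age_range = c(15, 49)), "no strata")
  expect_error(aggregate_excess(cells, by = "not_a_column"), "not present")
})

test_that("table1 layout has country rows plus totals consistent with the cells", {
  reg <- sample_registry(karabakh_preset())
  est <- fit_all(reg, "SYN", pi_draws = 500, seed = 4)
  ex <- compute_excess(dplyr::filter(reg, year == 2020), combine_envelope(est))
  tab <- table1_report(ex)
  expect_equal(tab$country, c("SYN", "Total"))
  expect_match(tab$male[1], "^-?\\d+ \\[-?\\d+, -?\\d+\\]$")
  expect_equal(tab$male[1], tab$male[2]) # single country: total row equals it
})
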