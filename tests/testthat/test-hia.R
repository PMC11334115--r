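heat_erf <- function(beta, threshold = 18.9, rel = 0.2) {
  exposure_response(threshold, data.frame(
    stratum = names(beta), central = unname(beta),
    low = unname(beta) * (1 - rel), high = unname(beta) * (1 + rel)))
}

test_that("relative risk is clamped at the threshold and log-linear above it", {
  erf <- heat_erf(c(all = log(1.01)))
  expect_equal(relative_risk(18.9, erf, "all"), 1)
  expect_equal(relative_risk(13.9, erf, "all"), 1)
  expect_equal(relative_risk(28.9, erf, "all"), 1.01^10, tolerance = 1e-12)
  expect_equal(1.01^10, 1.104622, tolerance = 1e-6)
  expect_error(relative_risk(20, erf, "nope"), "unknown stratum")
  expect_error(relative_risk(NaN, erf, "all"), "non-finite")
})

test_that("attributable fraction is (RR-1)/RR", {
  expect_equal(attributable_fraction(1), 0)
  expect_equal(attributable_fraction(2), 0.5)
  expect_equal(attributable_fraction(1.25), 0.2)
  expect_error(attributable_fraction(0), "positive")
})

test_that("heat attribution: sub-threshold zero, single-day arithmetic, scale consistency", {
  erf <- heat_erf(c(all = 0.05))
  x <- make_daily_series(c(15, 16, 17))
  m <- make_mortality(matrix(c(100, 100, 100), 3), strata = "all")
  res <- attribute_heat(x, m, erf)
  expect_true(all(res$daily$attributable_deaths == 0))

  # one day, RR = 1.25 by construction, M = 100 -> AD = 20
  beta <- log(1.25) / 5
  erf1 <- heat_erf(c(all = beta))
  x1 <- make_daily_series(18.9 + 5)
  m1 <- make_mortality(matrix(100, 1), strata = "all")
  res1 <- attribute_heat(x1, m1, erf1)
  expect_equal(attribution_total(res1), 20, tolerance = 1e-12)

  # doubling mortality doubles every attributable number exactly
  m2 <- m1; m2$deaths <- m2$deaths * 2
  res2 <- attribute_heat(x1, m2, erf1)
  expect_equal(res2$daily$attributable_deaths,
               2 * res1$daily$attributable_deaths, tolerance = 1e-15)
})

test_that("heat attribution equals the single-loop oracle on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    nd <- sample(3:10, 1); ns <- sample(1:3, 1)
    x <- runif(nd, 15, 30)
    m <- matrix(rpois(nd * ns, 80), nd, ns)
    beta <- runif(ns, 0, 0.06)
    strata <- paste0("s", seq_len(ns))
    erf <- heat_erf(setNames(beta, strata))
    res <- attribute_heat(make_daily_series(x), make_mortality(m, strata = strata), erf)
    expect_equal(attribution_total(res),
                 brute_attribution(x, m, beta, 18.9),
                 tolerance = 1e-12)
  }
})

test_that("attribution totals are additive and ordered across coefficient quantiles", {
  set.seed(11)
  x <- runif(8, 17, 30)
  m <- matrix(rpois(24, 60), 8, 3)
  erf <- heat_erf(c(a = 0.02, b = 0.03, c = 0.05))
  res <- attribute_heat(make_daily_series(x), make_mortality(m, strata = c("a", "b", "c")), erf)
  for (q in c("central", "low", "high")) {
    tot <- attribution_total(res, q)
    by_str <- res$totals_by_stratum
    expect_equal(tot, sum(by_str$attributable_deaths[by_str$quantile == q]),
                 tolerance = 1e-12)
    d <- res$daily
    expect_equal(tot, sum(d$attributable_deaths[d$quantile == q]),
                 tolerance = 1e-12)
  }
  expect_lte(attribution_total(res, "low"), attribution_total(res, "central"))
  expect_lte(attribution_total(res, "central"), attribution_total(res, "high"))
})

test_that("attributable deaths are monotone in exposure for positive beta", {
  erf <- heat_erf(c(all = 0.03))
  m <- make_mortality(matrix(100, 5), strata = "all")
  x1 <- make_daily_series(c(17, 19, 21, 23, 25))
  x2 <- make_daily_series(c(17, 19, 23, 23, 25))  # one day raised
  expect_gt(attribution_total(attribute_heat(x2, m, erf)),
            attribution_total(attribute_heat(x1, m, erf)))
})

test_that("missing exposure or mismatched strata inside the period abort", {
  erf <- heat_erf(c(all = 0.03))
  x <- make_daily_series(c(20, 21, 22))
  m <- make_mortality(matrix(50, 3), strata = "all")
  expect_error(attribute_heat(x, m, erf,
                              period = c(x$date[1], x$date[3] + 2)),
               "exposure missing")
  m_bad <- m; m_bad$age_group <- "other"
  expect_error(attribute_heat(x, m_bad, erf), "strata")
})

test_that("UHI attribution is the paired scenario difference", {
  erf <- heat_erf(c(a = 0.02, b = 0.04))
  set.seed(12)
  m <- make_mortality(matrix(rpois(12, 70), 6, 2), strata = c("a", "b"))
  xu <- make_daily_series(runif(6, 20, 30), scenario = "urban")
  xn <- make_daily_series(xu$value - runif(6, 0, 3), scenario = "non-urban")
  ru <- attribute_heat(xu, m, erf)
  rn <- attribute_heat(xn, m, erf)
  uhi <- attribute_uhi(ru, rn)

  expect_equal(attribution_total(uhi),
               attribution_total(ru) - attribution_total(rn), tolerance = 1e-12)
  # paired per-day, per-stratum, per-quantile difference
  key <- function(d) paste(d$date, d$stratum, d$quantile)
  nu <- rn$daily[match(key(ru$daily), key(rn$daily)), ]
  expect_equal(uhi$daily$attributable_deaths,
               ru$daily$attributable_deaths - nu$attributable_deaths,
               tolerance = 1e-12)

  # identical scenarios give exactly zero
  zero <- attribute_uhi(ru, ru)
  expect_true(all(zero$daily$attributable_deaths == 0))

  # non-urban entirely below threshold: UHI equals the urban result
  xn0 <- make_daily_series(rep(15, 6), scenario = "non-urban")
  rn0 <- attribute_heat(xn0, m, erf)
  uhi0 <- attribute_uhi(ru, rn0)
  expect_equal(attribution_total(uhi0), attribution_total(ru), tolerance = 1e-12)

  ru_short <- attribute_heat(xu, m, erf, period = c(xu$date[1], xu$date[5]))
  expect_error(attribute_uhi(ru, ru_short), "different periods")
})

test_that("pollutant attribution reproduces the closed-form examples", {
  # zero concentration -> zero attributable
  conc0 <- make_daily_series(rep(0, 3), metric = "daily_max_8h_mean")
  m <- make_mortality(matrix(500, 3), strata = "all")
  expect_equal(attribution_total(attribute_pollutant(conc0, m, 0.34, c(0.12, 0.56))),
               0)

  # ozone coefficient, C = 10 sustained, M = 1000 on one day
  conc1 <- make_daily_series(10, metric = "daily_max_8h_mean")
  m1 <- make_mortality(matrix(1000, 1), strata = "all")
  r1 <- attribute_pollutant(conc1, m1, 0.34, c(0.12, 0.56))
  expect_equal(attribution_total(r1), 1000 * 0.0034 / 1.0034, tolerance = 1e-9)
  expect_equal(attribution_total(r1), 3.388, tolerance = 1e-3)

  # PM2.5 coefficient, C = 20, M = 500 (log-linear reading)
  conc2 <- make_daily_series(20, metric = "daily_max_8h_mean")
  m2 <- make_mortality(matrix(500, 1), strata = "all")
  r2 <- attribute_pollutant(conc2, m2, 1.04, c(0.52, 1.56))
  rr <- 1.0104^2
  expect_equal(attribution_total(r2), 500 * (rr - 1) / rr, tolerance = 1e-9)

  # linear option stays within 0.03% of log-linear at these levels
  r2l <- attribute_pollutant(conc2, m2, 1.04, c(0.52, 1.56), form = "linear")
  expect_equal(attribution_total(r2l), attribution_total(r2), tolerance = 6e-3)

  expect_error(attribute_pollutant(make_daily_series(-1, metric = "daily_max_8h_mean"),
                                   m2, 1.04, c(0.52, 1.56)),
               "negative")
})

test_that("pollutant attribution matches the single-loop oracle and uses all-ages deaths", {
  for (seed in 1:5) {
    set.seed(seed)
    nd <- sample(3:10, 1)
    conc <- runif(nd, 0, 120)
    m3 <- matrix(rpois(nd * 3, 40), nd, 3)
    res <- attribute_pollutant(make_daily_series(conc, metric = "daily_max_8h_mean"),
                               make_mortality(m3), 0.34, c(0.12, 0.56))
    expect_equal(attribution_total(res),
                 brute_pollutant(conc, rowSums(m3), 0.34), tolerance = 1e-12)
  }
})

test_that("fit_erf recovers the coefficient exactly from noiseless counts", {
  set.seed(13)
  x <- c(runif(30, 14, 18), runif(60, 19, 30))
  xs <- make_daily_series(x, metric = "daily_mean", scenario = "t")
  lam <- 150 * exp(0.03 * pmax(0, x - 18.9))
  m <- data.frame(date = xs$date, age_group = "all", deaths = lam)  # exact Poisson means
  erf <- fit_erf(xs, m, threshold = 18.9)
  expect_equal(erf$coef$central, 0.03, tolerance = 1e-6)
})

test_that("fit_erf refuses unidentifiable data", {
  xs <- make_daily_series(rep(15, 40), metric = "daily_mean")
  m <- data.frame(date = xs$date, age_group = "all", deaths = rpois(40, 100))
  expect_error(fit_erf(xs, m), "unidentifiable")
})

test_that("with no planted effect the Wald CI covers zero at nominal rate", {
  set.seed(14)
  x <- runif(60, 15, 30)
  xs <- make_daily_series(x, metric = "daily_mean")
  hits <- vapply(1:100, function(i) {
    m <- data.frame(date = xs$date, age_group = "all", deaths = rpois(60, 120))
    erf <- fit_erf(xs, m, threshold = 18.9)
    erf$coef$low <= 0 && 0 <= erf$coef$high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("conditional pollution comparison: identity, known ratio, filter oracle", {
  d <- as.Date("2003-07-01") + 0:19
  set.seed(15)
  tmax <- data.frame(date = d, value = runif(20, 25, 36))
  conc <- data.frame(date = d, value = runif(20, 10, 60))
  same <- conditional_pollution_summary(conc, tmax, conc, tmax, 30)
  expect_equal(same$ratio, 1)
  expect_equal(same$percent_diff, 0)

  conc3 <- conc; conc3$value <- conc$value * 3
  trip <- conditional_pollution_summary(conc, tmax, conc3, tmax, 30)
  expect_equal(trip$ratio, 3, tolerance = 1e-12)
  expect_equal(trip$percent_diff, 200, tolerance = 1e-12)

  hot <- tmax$value > 30
  expect_equal(same$mean_a, mean(conc$value[hot]), tolerance = 1e-12)
  expect_equal(same$n_days_a, sum(hot))

  cold <- tmax; cold$value <- rep(20, 20)
  expect_error(conditional_pollution_summary(conc, cold, conc, cold, 30),
               "no days above")
})
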