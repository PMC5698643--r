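test_that("OLS trend recovers exact and simulated slopes", {
  d <- tibble::tibble(year = 2001:2010, y = 2 * (2001:2010))
  tr <- ols_trend(d, y)
  expect_equal(tr$beta, 2, tolerance = 1e-10)
  expect_equal(tr$r, 1)
  expect_equal(tr$p, 0)
  expect_equal(tr$delta, 2 * 10)

  # constant series: zero slope, zero change, flagged
  expect_warning(trc <- ols_trend(tibble::tibble(year = 2001:2010, y = 5), y),
                 "zero variance")
  expect_equal(trc$beta, 0)
  expect_equal(trc$delta, 0)
  expect_true(trc$zero_variance)

  # slope CI coverage at the generating slope (38-year series, sd-1 noise)
  set.seed(11)
  covered <- vapply(1:500, function(i) {
    dd <- tibble::tibble(year = 1:38, y = 0.05 * (1:38) + rnorm(38))
    t1 <- ols_trend(dd, y)
    abs(t1$beta - 0.05) <= 2 * t1$se
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("total change converts slopes over the study span", {
  expect_equal(total_change(0)$delta, 0)
  expect_equal(total_change(0.1, span_years = 10)$delta, 1)
  expect_equal(total_change(-0.02)$delta_1dp, -0.8)
})

test_that("AR-error AIC comparison separates white-noise from AR residuals", {
  set.seed(21)
  sel_white <- vapply(1:60, function(i) {
    d <- tibble::tibble(year = 1:38, y = 0.05 * (1:38) + rnorm(38))
    cmp <- gls_ar_compare(d, y)
    cmp$aic_ols <= cmp$aic_ar1
  }, logical(1))
  expect_gte(mean(sel_white), 0.8)

  sel_ar <- vapply(1:60, function(i) {
    e <- as.numeric(stats::filter(rnorm(38), 0.8, method = "recursive"))
    d <- tibble::tibble(year = 1:38, y = 0.05 * (1:38) + e)
    gls_ar_compare(d, y)$selected
  }, character(1))
  expect_gte(mean(sel_ar == "ar1"), 0.8)

  # minimal input returns finite AICs or flagged failures without crashing
  cmp6 <- gls_ar_compare(tibble::tibble(year = 1:6, y = rnorm(6)), y)
  expect_true(is.finite(cmp6$aic_ols))
  expect_equal(nrow(cmp6), 1)
})

test_that("normalized trend is scale-free", {
  set.seed(31)
  d <- tibble::tibble(year = 1:20, y = 2 + 0.01 * (1:20) + rnorm(20, 0, 0.1))
  n1 <- normalized_trend(d, y)
  d3 <- dplyr::mutate(d, y = 3 * y)
  expect_equal(normalized_trend(d3, y)$beta_normalized, n1$beta_normalized,
               tolerance = 1e-12)
  suppressWarnings(
    expect_equal(normalized_trend(tibble::tibble(year = 1:10, y = 4),
                                  y)$beta_normalized, 0))
  expect_error(normalized_trend(tibble::tibble(year = 1:10, y = -(1:10)), y),
               "positive")
})

test_that("log-ratio trend measures relative divergence", {
  yrs <- 1:30
  d <- tibble::tibble(year = yrs, a = 5 + 0.1 * yrs, b = 5 + 0.1 * yrs)
  suppressWarnings(eq <- log_ratio_trend(d, a, b))
  expect_equal(eq$beta, 0)
  expect_equal(eq$t, 0)

  # exact exponential divergence
  d2 <- tibble::tibble(year = yrs, b = 5 + 0.1 * yrs)
  d2$a <- d2$b * exp(0.01 * yrs)
  ex <- log_ratio_trend(d2, a, b)
  expect_equal(ex$beta, 0.01, tolerance = 1e-10)

  # non-positive years dropped with a warning
  d3 <- d2
  d3$a[5] <- -1
  expect_warning(dr <- log_ratio_trend(d3, a, b), "non-positive")
  expect_equal(dr$n, 29)

  # equal proportional trends: type-I error near alpha
  set.seed(41)
  rej <- vapply(1:400, function(i) {
    base <- exp(0.02 * yrs)
    dd <- tibble::tibble(year = yrs,
                         a = base * exp(rnorm(30, 0, 0.2)),
                         b = base * exp(rnorm(30, 0, 0.2)))
    log_ratio_trend(dd, a, b)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("slope-difference test behaves under equality and construction", {
  d <- tibble::tibble(year = 1:20, y = 1:20 + c(rep(0, 10), rep(1, 10)))
  f <- ols_trend(d, y)
  same <- slope_difference_test(f, f)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # beta1 - beta2 = 3 * pooled se gives |t| = 3
  f1 <- tibble::tibble(beta = 0.5, se = 0.1, n = 30)
  f2 <- tibble::tibble(beta = 0.5 - 3 * sqrt(0.02), se = 0.1, n = 30)
  expect_equal(abs(slope_difference_test(f1, f2)$t), 3, tolerance = 1e-12)

  # equal generating slopes: rejection near alpha
  set.seed(51)
  rej <- vapply(1:400, function(i) {
    da <- tibble::tibble(year = 1:30, y = 0.1 * (1:30) + rnorm(30))
    db <- tibble::tibble(year = 1:30, y = 0.1 * (1:30) + rnorm(30))
    slope_difference_test(ols_trend(da, y), ols_trend(db, y))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("temperature response regresses metric on window temperature", {
  d <- tibble::tibble(t = rnorm(20, 5), m = NA)
  d$m <- 0.1 * d$t
  fit <- temp_response(d, m, t)
  expect_equal(fit$beta, 0.1, tolerance = 1e-10)
  expect_equal(fit$r, 1)

  # independent series: about 5% significant
  set.seed(61)
  rej <- vapply(1:400, function(i) {
    dd <- tibble::tibble(t = rnorm(38), m = rnorm(38))
    temp_response(dd, m, t)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("partial regression separates temperature from covariates", {
  set.seed(71)
  # covariates orthogonal to both metric and temperature leave beta unchanged
  n <- 40
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, 0, 0.3)
  z1 <- residuals(lm(rnorm(n) ~ x + y))
  z2 <- residuals(lm(rnorm(n) ~ x + y + z1))
  d <- tibble::tibble(m = y, t = x, rodent_sqrt = z1, fox_log = z2)
  pr <- partial_regression(d, m, t)
  expect_equal(pr$beta_partial, temp_response(d, m, t)$beta, tolerance = 1e-10)

  # metric fully explained by the covariates: beta_p ~ 0
  d2 <- tibble::tibble(t = rnorm(n), rodent_sqrt = rnorm(n), fox_log = rnorm(n))
  d2$m <- 2 * d2$rodent_sqrt - d2$fox_log
  expect_lt(abs(suppressWarnings(partial_regression(d2, m, t))$beta_partial),
            1e-10)

  # Frisch-Waugh: residual-on-residual slope equals the multiple-regression
  # coefficient on arbitrary correlated data
  for (i in 1:20) {
    nn <- sample(15:40, 1)
    zz <- matrix(rnorm(nn * 2), nn)
    tt <- rnorm(nn) + 0.4 * zz[, 1]
    mm <- rnorm(nn) + 0.3 * tt - 0.2 * zz[, 2]
    dd <- tibble::tibble(m = mm, t = tt, rodent_sqrt = zz[, 1], fox_log = zz[, 2])
    expect_equal(partial_regression(dd, m, t)$beta_partial,
                 residual_slope(dd, m, t),
                 tolerance = 1e-10)
  }
})

test_that("covariate transforms handle zeros and report them", {
  cov <- tibble::tibble(year = 1:4, rodent_index = c(0, 1, 4, 9),
                        fox_index = c(0, 0.5, 1, 2))
  expect_warning(tc <- transform_covariates(cov), "zero fox")
  expect_equal(tc$rodent_sqrt, c(0, 1, 2, 3))
  expect_equal(tc$fox_log[2], log(0.5 + 0.25))
  expect_error(transform_covariates(dplyr::mutate(cov, fox_index = -1)),
               "non-negative")
})

test_that("lagged summer response aligns years correctly", {
  set.seed(81)
  summer <- tibble::tibble(year = 2000:2019, t_summer = rnorm(20, 13))
  met <- tibble::tibble(year = 2000:2019, m = NA_real_)
  met$m[2:20] <- summer$t_summer[1:19]   # metric equals lag-1 temperature
  res <- lagged_response(met, summer, m, lags = 1)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)

  # independent series: mean R^2 near 1/(n-1)
  rsq <- vapply(1:400, function(i) {
    mm <- tibble::tibble(year = 2000:2019, m = rnorm(20))
    lagged_response(mm, summer, m, lags = 1)$r_squared
  }, numeric(1))
  expect_equal(mean(rsq), 1 / (19 - 1), tolerance = 0.02)

  # lag 2 on a 3-year series leaves too little overlap
  short_m <- tibble::tibble(year = 2000:2002, m = rnorm(3))
  short_s <- tibble::tibble(year = 2000:2002, t_summer = rnorm(3))
  expect_error(lagged_response(short_m, short_s, m, lags = 2), "fewer than 3")
})
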