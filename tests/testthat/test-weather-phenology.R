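test_that("lapse-rate adjustment shifts temperatures and preserves structure", {
  w <- make_weather(2000, t_avg = 5, t_min = 0, t_max = 10)
  adj <- adjust_lapse_rate(w, phenology_config(elevation_diff = 200))
  expect_equal(adj$t_min[1], -1.3)
  expect_equal(adj$t_avg[1], 3.7)
  expect_equal(adj$t_max[1], 8.7)
  expect_true(all(adj$t_min <= adj$t_avg & adj$t_avg <= adj$t_max))
  expect_equal(adj$precip, w$precip)
  expect_equal(adj$snow_score, w$snow_score)

  # site 100 m above the station: 10.0 -> 9.35 at the 0.65/100 m lapse
  one <- adjust_lapse_rate(make_weather(2000, t_avg = 10),
                           phenology_config(elevation_diff = 100))
  expect_equal(one$t_avg[1], 9.35)

  # identity at zero elevation difference, and after +e then -e
  expect_equal(adjust_lapse_rate(w, phenology_config(elevation_diff = 0)), w)
  back <- adjust_lapse_rate(adj, phenology_config(elevation_diff = -200))
  expect_equal(back$t_avg, w$t_avg, tolerance = 1e-12)
})

test_that("frost-free date is the centre of the first positive 7-day window", {
  # never crosses
  cold <- make_weather(2001, t_avg = 4, t_min = -1)
  expect_true(is.na(frost_free_date(cold)$frost_free_doy))

  # linear ramp t_min = 0.2 * (doy - 100): centred mean is the centre
  # value, first positive at doy 101
  ramp <- make_weather(2001, t_avg = function(d) 0.2 * (d - 100) + 5,
                       t_min = function(d) 0.2 * (d - 100))
  expect_equal(frost_free_date(ramp)$frost_free_doy, 101)

  # brute-force scan oracle over the same series
  tmin <- 0.2 * ((1:181) - 100)
  ma <- vapply(4:178, function(d) mean(tmin[(d - 3):(d + 3)]), numeric(1))
  expect_equal(frost_free_date(ramp)$frost_free_doy, (4:178)[which(ma > 0)[1]])

  # always-warm series: earliest computable centred window, day 4
  warm <- make_weather(2001, t_avg = 8, t_min = 3)
  expect_equal(frost_free_date(warm)$frost_free_doy, 4)

  # monotone: uniformly warmer never yields a later date
  warmer <- ramp
  warmer$t_min <- warmer$t_min + 2
  expect_lte(frost_free_date(warmer)$frost_free_doy,
             frost_free_date(ramp)$frost_free_doy)

  # a gap in spring coverage is an explicit error
  gap <- ramp[-60, ]
  expect_error(frost_free_date(gap), "gap")
})

test_that("snow-free date is the earliest qualifying score", {
  w <- make_weather(2001, t_avg = 5, snow_score = 5L)
  w$snow_score[w$date >= as.Date("2001-03-31") &
                 w$date <= as.Date("2001-04-04")] <- c(5L, 3L, 1L, 0L, 0L)
  w$snow_score[w$date > as.Date("2001-04-04")] <- 0L
  doy90 <- as.POSIXlt(as.Date("2001-03-31"))$yday + 1
  expect_equal(doy90, 90)
  expect_equal(snow_free_date(w)$snow_free_doy, 93)

  # all zero scores: first day of the year
  expect_equal(snow_free_date(make_weather(2001, snow_score = 0L))$snow_free_doy, 1)

  # first-occurrence rule when cover returns later
  w2 <- make_weather(2001, snow_score = 5L)
  w2$snow_score[100:103] <- c(1L, 0L, 2L, 0L)
  expect_equal(snow_free_date(w2)$snow_free_doy, 101)

  # never snow-free is NA; all-missing scores is an error
  expect_true(is.na(snow_free_date(make_weather(2001, snow_score = 3L))$snow_free_doy))
  w3 <- make_weather(2001)
  w3$snow_score <- NA_integer_
  expect_error(snow_free_date(w3), "missing")
})

test_that("GDD accumulation matches hand sums and the onset matches brute force", {
  cfg <- phenology_config()
  # constant 15 C, base 5: +10/day, 200 reached on day 20
  w15 <- make_weather(2001, t_avg = 15)
  acc <- gdd_accumulate(w15, cfg)
  expect_equal(acc$gdd[1:3], c(10, 20, 30))
  expect_equal(gdd_onset_date(w15, cfg)$gdd200_doy, 20)

  # at the base temperature nothing accumulates
  w5 <- make_weather(2001, t_avg = 5)
  expect_true(all(gdd_accumulate(w5, cfg)$gdd == 0))
  expect_true(is.na(gdd_onset_date(w5, cfg)$gdd200_doy))

  # alternating 0/20: contributes 0, 15 alternating, day 2k totals 15k
  walt <- make_weather(2001, t_avg = function(d) ifelse(d %% 2 == 1, 0, 20))
  acc_alt <- gdd_accumulate(walt, cfg)
  k <- 1:50
  expect_equal(acc_alt$gdd[2 * k], 15 * k)

  # degenerate threshold: first accumulating day
  expect_equal(gdd_onset_date(w15, phenology_config(gdd_threshold = 1e-9))$gdd200_doy, 1)

  # random series vs an independent brute-force scan
  set.seed(401)
  for (i in 1:20) {
    tv <- runif(365, 0, 18)
    wr <- make_weather(2001, t_avg = function(d) tv[d])
    brute <- which(cumsum(pmax(tv - 5, 0)) >= 200)[1]
    got <- gdd_onset_date(wr, cfg)$gdd200_doy
    expect_equal(got, if (is.na(brute)) NA_integer_ else brute)
    expect_true(all(diff(gdd_accumulate(wr, cfg)$gdd) >= 0))
  }

  # missing t_avg inside the range is an error
  wna <- w15
  wna$t_avg[50] <- NA
  expect_error(gdd_accumulate(wna, cfg), "missing")
})

test_that("window means equal brute force and tile to the global mean", {
  # constant series
  expect_equal(window_mean(make_weather(2001, t_avg = 7), 2001, 120, 150), 7)

  # April t_min rising linearly 0..2.9: mean 1.45 (April = doy 91..120 in 2001)
  wapr <- make_weather(2001, t_avg = 10,
                       t_min = function(d) ifelse(d >= 91 & d <= 120,
                                                  (d - 91) * 0.1, 0))
  expect_equal(window_mean(wapr, 2001, 91, 120, which = "min"), 1.45)

  # random windows vs brute-force sum/length
  set.seed(402)
  tv <- rnorm(365, 5, 3)
  wr <- make_weather(2001, t_avg = function(d) tv[d])
  for (i in 1:25) {
    a <- sample(1:300, 1)
    b <- a + sample(0:60, 1)
    expect_equal(window_mean(wr, 2001, a, b), sum(tv[a:b]) / (b - a + 1),
                 tolerance = 1e-12)
  }

  # 13 weekly periods tiling 1 Apr - 30 Jun average to the 91-day mean
  per <- season_periods(2001)
  wm <- window_means(wr, per, vars = "t_avg")
  expect_equal(nrow(wm), 13)
  expect_equal(mean(wm$t_avg_mean), window_mean(wr, 2001, 91, 181),
               tolerance = 1e-12)

  # missing day inside a window errors with the gap count
  wna <- wr
  wna$t_avg[c(100, 105)] <- NA
  expect_error(window_means(wna, tibble::tibble(year = 2001, start_doy = 95,
                                                end_doy = 110), vars = "t_avg"),
               "2 day")
})

test_that("monthly means agree with direct computation", {
  set.seed(403)
  tv <- rnorm(730, 8, 4)
  w <- make_weather(2001:2002, t_avg = function(d) NA) # placeholder
  w$t_avg <- tv
  w$t_min <- tv - 5
  w$t_max <- tv + 5
  mm <- monthly_means(w, months = 4:6)
  expect_equal(nrow(mm), 6)
  april02 <- w$t_avg[format(w$date, "%Y-%m") == "2002-04"]
  expect_equal(mm$t_avg_mean[mm$year == 2002 & mm$month == 4], mean(april02))
})

test_that("weather validation catches ordering and domain violations", {
  w <- make_weather(2001)
  expect_silent(validate_weather(w))
  bad <- w
  bad$t_min[5] <- bad$t_max[5] + 1
  expect_error(validate_weather(bad), "t_min")
  dup <- dplyr::bind_rows(w, w[1, ])
  expect_error(validate_weather(dup), "increasing")
})
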