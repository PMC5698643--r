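# Calendar and small numerical helpers shared across modules.

is_leap <- function(year) (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0

#' Day of year for a date (1-based)
#' @param date a `Date` vector
#' @return integer day-of-year, 1 = 1 January
#' @export
day_of_year <- function(date) as.POSIXlt(date)$yday + 1L

# doy of 30 June, the end of the spring scan (181, or 182 in leap years)
june30_doy <- function(year) 181L + is_leap(year)

# doy of 1 April (91, or 92 in leap years)
april1_doy <- function(year) 91L + is_leap(year)

# add year/doy columns to a daily weather tibble
add_calendar <- function(weather) {
  if (!"year" %in% names(weather)) {
    weather$year <- as.integer(format(weather$date, "%Y"))
  }
  if (!"doy" %in% names(weather)) {
    weather$doy <- day_of_year(weather$date)
  }
  weather
}

# centered moving average, width must be odd; NA at the edges
moving_average <- function(x, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

# mean-zero AR(1) noise, phi in (-1, 1), innovation sd
ar1_noise <- function(n, phi, sd) {
  as.numeric(stats::filter(rnorm(n, 0, sd), phi, method = "recursive"))
}

# small-sample corrected AIC for an lm/gls fit
aicc <- function(fit) {
  k <- attr(logLik(fit), "df")
  n <- stats::nobs(fit)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

# simple regression of y on x returning slope, se, r, p with pairwise
# complete cases; the workhorse behind the trend battery
lm_xy <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort(sprintf("need at least 3 paired observations, got %d", n))
  }
  if (stats::var(x) == 0) {
    abort("predictor has zero variance; slope undefined")
  }
  fit <- lm(y ~ x)
  beta <- unname(coef(fit)[2])
  sigma2 <- sum(residuals(fit)^2) / (n - 2)
  se <- sqrt(sigma2 / sum((x - mean(x))^2))
  zero_var_y <- stats::var(y) == 0
  # a numerically perfect line: report r = +/-1, p = 0 rather than NaN
  if (!zero_var_y && sigma2 < 1e-24 * stats::var(y)) {
    r <- sign(beta)
    p <- 0
  } else if (zero_var_y) {
    r <- NA_real_
    p <- NA_real_
  } else {
    r <- cor(x, y)
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(n = n, beta = beta, se = se, r = r, p = p, fit = fit,
       zero_variance = zero_var_y)
}

# check a data frame has the given columns
check_columns <- function(data, cols, what) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(data)
}
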