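# The trend / regression battery: OLS year trends with AR-error GLS
# comparison, total-change conversion, normalized and log-ratio
# interspecific comparisons, climate-window responses, partial regressions
# controlling for rodents and fox, and lagged summer-temperature tests.
# Two-sided p-values throughout; no multiple-testing correction is applied,
# matching the reporting convention of long-term single-population studies
# (interpret tables accordingly).

#' Ordinary least-squares trend of an annual series
#'
#' Regresses an annual variable on calendar year, dropping missing years
#' pairwise. Reports the slope (per year), its standard error, the Pearson
#' correlation with year, the two-sided p-value, and the total change
#' `delta = beta * span_years` over the study period.
#'
#' @param data tibble holding one row per year.
#' @param value column to regress (tidy-eval).
#' @param year year column (tidy-eval, default `year`).
#' @param span_years years spanned by the study used for the total change;
#'   default `max(year) - min(year) + 1` (a 1979--2016 study spans 38).
#' @return one-row tibble `variable`, `n`, `beta`, `se`, `r`, `p`, `delta`,
#'   `span_years`, `zero_variance`.
#' @examples
#' d <- tibble::tibble(year = 2001:2010, y = 2 * (2001:2010))
#' ols_trend(d, y)
#' @export
ols_trend <- function(data, value, year = year, span_years = NULL) {
  yv <- dplyr::pull(data, {{ value }})
  xv <- dplyr::pull(data, {{ year }})
  ok <- complete.cases(xv, yv)
  span <- span_years %||% (max(xv[ok]) - min(xv[ok]) + 1)
  res <- lm_xy(xv, yv)
  if (res$zero_variance) {
    warn("response has zero variance: r and p undefined, beta = 0")
    res$beta <- 0
  }
  tibble::tibble(variable = rlang::as_name(rlang::enquo(value)),
                 n = res$n, beta = res$beta, se = res$se, r = res$r,
                 p = res$p, delta = res$beta * span, span_years = span,
                 zero_variance = res$zero_variance)
}

#' Convert a yearly slope to total change over the study period
#'
#' `delta = beta * span_years`, with the value also rounded to one decimal
#' as conventionally printed (e.g. an April daily-minimum slope of 0.050
#' degrees C per year over a 38-year study is a 1.9 degree rise).
#'
#' @param beta numeric vector of yearly slopes.
#' @param span_years study-period length in years (default 38).
#' @return tibble `beta`, `span_years`, `delta`, `delta_1dp`.
#' @export
total_change <- function(beta, span_years = 38) {
  stopifnot(all(is.finite(beta)))
  tibble::tibble(beta = beta, span_years = span_years,
                 delta = beta * span_years,
                 delta_1dp = round(beta * span_years, 1))
}

#' Compare independent-, AR(1)- and AR(2)-error trend models by AIC
#'
#' Fits the year-trend model by maximum likelihood with independent errors
#' and with AR(1) and AR(2) residual correlation (via [nlme::gls()]), and
#' reports the three AICs and the minimum-AIC model. Low, non-significant
#' autocorrelation shows up as the independent-error model having similar
#' or lower AIC, justifying plain OLS reporting. Non-convergence of an AR
#' fit is reported (`NA` AIC), not fatal.
#'
#' @inheritParams ols_trend
#' @return one-row tibble `n`, `aic_ols`, `aic_ar1`, `aic_ar2`, `selected`.
#' @export
gls_ar_compare <- function(data, value, year = year) {
  yv <- dplyr::pull(data, {{ value }})
  xv <- dplyr::pull(data, {{ year }})
  ok <- complete.cases(xv, yv)
  d <- data.frame(y = yv[ok], x = xv[ok])
  if (nrow(d) < 6) abort("need at least 6 years for the AR comparison")
  fit_one <- function(corr) {
    tryCatch(AIC(nlme::gls(y ~ x, data = d, correlation = corr, method = "ML")),
             error = function(e) NA_real_)
  }
  aics <- c(ols = fit_one(NULL),
            ar1 = fit_one(nlme::corAR1(form = ~x)),
            ar2 = fit_one(nlme::corARMA(p = 2, form = ~x)))
  sel <- if (all(is.na(aics))) NA_character_ else names(which.min(aics))
  tibble::tibble(n = nrow(d), aic_ols = aics[["ols"]], aic_ar1 = aics[["ar1"]],
                 aic_ar2 = aics[["ar2"]], selected = sel)
}

#' Normalized (relative) trend
#'
#' The yearly slope divided by the series mean: a scale-free trend per year
#' that makes slopes of series on different scales (e.g. brood frequency in
#' proportion units vs brood size in chicks) directly comparable.
#'
#' @inheritParams ols_trend
#' @return one-row tibble `variable`, `n`, `beta`, `mean`,
#'   `beta_normalized`.
#' @export
normalized_trend <- function(data, value, year = year) {
  tr <- ols_trend(data, {{ value }}, {{ year }})
  yv <- dplyr::pull(data, {{ value }})
  m <- mean(yv, na.rm = TRUE)
  if (m <= 0) abort("normalized trend requires a positive series mean")
  tibble::tibble(variable = tr$variable, n = tr$n, beta = tr$beta, mean = m,
                 beta_normalized = tr$beta / m)
}

#' Log-ratio trend between two positive annual series
#'
#' Regresses `log(a / b)` on year: a direct test of whether two series'
#' proportional trends differ. Years where either series is non-positive
#' are dropped with a warning.
#'
#' @param data tibble with a year column and the two series.
#' @param a,b columns of the two series (tidy-eval).
#' @inheritParams ols_trend
#' @return one-row tibble `n`, `beta`, `se`, `t`, `p`,
#'   `method = "log_ratio_trend"`.
#' @export
log_ratio_trend <- function(data, a, b, year = year) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  xv <- dplyr::pull(data, {{ year }})
  ok <- complete.cases(av, bv, xv)
  pos <- ok & av > 0 & bv > 0
  if (any(ok & !pos)) {
    warn(sprintf("%d year(s) with non-positive values dropped from the log ratio",
                 sum(ok & !pos)))
  }
  res <- lm_xy(xv[pos], log(av[pos] / bv[pos]))
  if (res$zero_variance) res$beta <- 0
  tval <- if (res$se > 0) res$beta / res$se else 0   # identical series: t = 0
  tibble::tibble(n = res$n, beta = res$beta, se = res$se,
                 t = tval, p = res$p,
                 method = "log_ratio_trend")
}

#' Test the difference between two independent regression slopes
#'
#' `t = (beta1 - beta2) / sqrt(se1^2 + se2^2)` with a Welch--Satterthwaite
#' degrees-of-freedom approximation built from the two fits' residual
#' degrees of freedom (`n - 2` each); two-sided p.
#'
#' @param fit1,fit2 one-row tibbles with columns `beta`, `se`, `n` (as
#'   returned by [ols_trend()] or [temp_response()]), from independent
#'   data sets.
#' @return one-row tibble `beta1`, `beta2`, `t`, `df`, `p`,
#'   `method = "difference_test"`.
#' @export
slope_difference_test <- function(fit1, fit2) {
  b1 <- fit1$beta; s1 <- fit1$se; df1 <- fit1$n - 2
  b2 <- fit2$beta; s2 <- fit2$se; df2 <- fit2$n - 2
  pooled <- sqrt(s1^2 + s2^2)
  if (pooled == 0) {
    if (b1 == b2) {
      return(tibble::tibble(beta1 = b1, beta2 = b2, t = 0, df = df1 + df2,
                            p = 1, method = "difference_test"))
    }
    abort("zero pooled standard error with unequal slopes")
  }
  tval <- (b1 - b2) / pooled
  df <- pooled^4 / (s1^4 / df1 + s2^4 / df2)
  tibble::tibble(beta1 = b1, beta2 = b2, t = tval, df = df,
                 p = 2 * pt(-abs(tval), df = df),
                 method = "difference_test")
}

#' Regression of an annual demographic metric on window temperature
#'
#' OLS of the metric on the annual mean temperature of a breeding-season
#' window (not on year), joined by year with pairwise complete cases.
#'
#' @param data tibble holding both annual series (join your metric and
#'   window-mean tables first, e.g. with [dplyr::left_join()]).
#' @param metric,temp columns for response and temperature (tidy-eval).
#' @return one-row tibble `response`, `predictor`, `n`, `beta`, `se`, `r`,
#'   `p`.
#' @export
temp_response <- function(data, metric, temp) {
  yv <- dplyr::pull(data, {{ metric }})
  xv <- dplyr::pull(data, {{ temp }})
  res <- lm_xy(xv, yv)
  tibble::tibble(response = rlang::as_name(rlang::enquo(metric)),
                 predictor = rlang::as_name(rlang::enquo(temp)),
                 n = res$n, beta = res$beta, se = res$se, r = res$r, p = res$p)
}

#' Transform right-skewed covariates
#'
#' Square-root transforms the small-rodent index and natural-log transforms
#' the red-fox index. Zero fox indices are handled by adding half the
#' smallest positive value before the log, with a warning.
#'
#' @param covariates tibble `year`, `rodent_index`, `fox_index`.
#' @return the tibble with added `rodent_sqrt` and `fox_log` columns.
#' @export
transform_covariates <- function(covariates) {
  check_columns(covariates, c("year", "rodent_index", "fox_index"), "covariates")
  if (any(covariates$rodent_index < 0, na.rm = TRUE) ||
      any(covariates$fox_index < 0, na.rm = TRUE)) {
    abort("covariate indices must be non-negative")
  }
  fox <- covariates$fox_index
  if (any(fox == 0, na.rm = TRUE)) {
    eps <- min(fox[fox > 0], na.rm = TRUE) / 2
    warn(sprintf("zero fox indices: using log(x + %.4g)", eps))
    fox <- fox + eps
  }
  dplyr::mutate(covariates, rodent_sqrt = sqrt(.data$rodent_index),
                fox_log = log(fox))
}

#' Partial regression of a metric on temperature, controlling for covariates
#'
#' Fits the multiple regression of the metric on window temperature plus
#' the transformed rodent and fox indices. The reported `beta_partial` is
#' the temperature coefficient; `r_partial` is the partial correlation
#' computed from the residual-on-residual regression (metric and
#' temperature each residualised on the covariates), which by the
#' Frisch--Waugh theorem has the same slope as the multiple-regression
#' coefficient. A near-singular design (condition number above `kappa_max`)
#' is flagged with a warning.
#'
#' @param data tibble holding the metric, the temperature and the
#'   covariate columns for matching years.
#' @param metric,temp columns for response and temperature (tidy-eval).
#' @param controls character vector of control column names (default the
#'   transformed `rodent_sqrt` and `fox_log`).
#' @param kappa_max condition-number guard (default 1e8).
#' @return one-row tibble `response`, `predictor`, `controls`, `n`,
#'   `beta_partial`, `se`, `r_partial`, `p`, `collinear`.
#' @export
partial_regression <- function(data, metric, temp,
                               controls = c("rodent_sqrt", "fox_log"),
                               kappa_max = 1e8) {
  check_columns(data, controls, "data")
  yv <- dplyr::pull(data, {{ metric }})
  xv <- dplyr::pull(data, {{ temp }})
  Z <- as.matrix(data[, controls, drop = FALSE])
  ok <- complete.cases(yv, xv, Z)
  yv <- yv[ok]; xv <- xv[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(yv)
  k <- ncol(Z)
  if (n < k + 3) abort(sprintf("need at least %d complete cases, got %d", k + 3, n))
  X <- cbind(1, xv, Z)
  collinear <- kappa(scale(X[, -1]), exact = TRUE) > kappa_max
  if (collinear) warn("near-singular design: partial coefficients unstable")
  fit <- lm(yv ~ xv + Z)
  sm <- summary(fit)$coefficients
  # residual-on-residual partial correlation
  ry <- residuals(lm(yv ~ Z))
  rx <- residuals(lm(xv ~ Z))
  tibble::tibble(response = rlang::as_name(rlang::enquo(metric)),
                 predictor = rlang::as_name(rlang::enquo(temp)),
                 controls = paste(controls, collapse = "+"),
                 n = n,
                 beta_partial = unname(coef(fit)["xv"]),
                 se = sm["xv", "Std. Error"],
                 r_partial = cor(ry, rx),
                 p = sm["xv", "Pr(>|t|)"],
                 collinear = collinear)
}

#' Residual-on-residual slope (Frisch--Waugh route)
#'
#' The slope of the metric's covariate-residuals on the temperature's
#' covariate-residuals: algebraically identical to the multiple-regression
#' temperature coefficient, exposed separately so the equivalence can be
#' verified on data.
#'
#' @inheritParams partial_regression
#' @return a single numeric slope.
#' @export
residual_slope <- function(data, metric, temp,
                           controls = c("rodent_sqrt", "fox_log")) {
  yv <- dplyr::pull(data, {{ metric }})
  xv <- dplyr::pull(data, {{ temp }})
  Z <- as.matrix(data[, controls, drop = FALSE])
  ok <- complete.cases(yv, xv, Z)
  ry <- residuals(lm(yv[ok] ~ Z[ok, , drop = FALSE]))
  rx <- residuals(lm(xv[ok] ~ Z[ok, , drop = FALSE]))
  unname(coef(lm(ry ~ rx))[2])
}

#' Mean summer temperature per year
#'
#' Mean daily average temperature over June--August, the summer covariate
#' used by the lagged-response test and the rodent coupling.
#'
#' @param weather daily weather tibble.
#' @return tibble `year`, `t_summer`.
#' @export
summer_mean_temp <- function(weather) {
  mm <- monthly_means(weather, months = 6:8)
  dplyr::summarise(dplyr::group_by(mm, .data$year),
                   t_summer = mean(.data$t_avg_mean), .groups = "drop")
}

#' Lagged summer-temperature response
#'
#' Regresses the annual metric on mean June--August temperature 1 and 2
#' years earlier (one OLS per lag, boundary years dropped by the
#' alignment), reporting R-squared and p per lag. Used to test delayed
#' food-plant-quality effects of warm summers.
#'
#' @param metrics tibble with `year` and the metric column.
#' @param summer tibble `year`, `t_summer` from [summer_mean_temp()].
#' @param metric metric column (tidy-eval).
#' @param lags integer lags in years (default `c(1, 2)`).
#' @return tibble `lag`, `n`, `beta`, `r_squared`, `p`.
#' @export
lagged_response <- function(metrics, summer, metric, lags = c(1, 2)) {
  yv <- dplyr::pull(metrics, {{ metric }})
  ytab <- tibble::tibble(year = metrics$year, y = yv)
  purrr::map_dfr(lags, function(l) {
    shifted <- dplyr::mutate(summer, year = .data$year + l)
    d <- dplyr::inner_join(ytab, shifted, by = "year")
    if (sum(complete.cases(d$y, d$t_summer)) < 3) {
      abort(sprintf("lag %d leaves fewer than 3 overlapping years", l))
    }
    res <- lm_xy(d$t_summer, d$y)
    tibble::tibble(lag = l, n = res$n, beta = res$beta,
                   r_squared = res$r^2, p = res$p)
  })
}
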