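# Derived phenology from daily weather: lapse-rate adjustment, onset dates
# (snow-free, frost-free, GDD threshold), monthly and window temperature
# means. A daily weather series is a tibble with columns
# date, t_min, t_avg, t_max, precip, snow_score.

#' Validate a daily weather series
#'
#' Checks the structural invariants of a daily weather tibble: strictly
#' increasing dates without duplicates, `t_min <= t_avg <= t_max` wherever
#' all three are present, non-negative precipitation, snow scores in 0--5
#' or missing.
#'
#' @param weather tibble with columns `date`, `t_min`, `t_avg`, `t_max`,
#'   `precip`, `snow_score`.
#' @return the input, invisibly, or an error describing the violation.
#' @export
validate_weather <- function(weather) {
  check_columns(weather, c("date", "t_min", "t_avg", "t_max"), "weather")
  if (is.unsorted(weather$date, strictly = TRUE)) {
    abort("weather dates must be strictly increasing with no duplicates")
  }
  full <- complete.cases(weather$t_min, weather$t_avg, weather$t_max)
  bad <- full & (weather$t_min > weather$t_avg | weather$t_avg > weather$t_max)
  if (any(bad)) {
    abort(sprintf("t_min <= t_avg <= t_max violated on %d day(s), first %s",
                  sum(bad), format(weather$date[which(bad)[1]])))
  }
  if ("precip" %in% names(weather) && any(weather$precip < 0, na.rm = TRUE)) {
    abort("precipitation must be non-negative")
  }
  if ("snow_score" %in% names(weather)) {
    s <- weather$snow_score
    if (any(!is.na(s) & !(s %in% 0:5))) abort("snow_score must be in 0..5 or NA")
  }
  invisible(weather)
}

#' Transfer station temperatures to the study site by lapse rate
#'
#' Shifts every daily temperature by `-lapse_rate * elevation_diff / 100`,
#' i.e. a site 100 m above the station at the default 0.65 degrees C / 100 m
#' lapse rate is 0.65 degrees colder. Precipitation and snow scores are
#' untouched and the day ordering is preserved.
#'
#' @param weather daily weather tibble (see [validate_weather()]).
#' @param config a [phenology_config()]; `elevation_diff` is the site
#'   elevation minus the station elevation in metres.
#' @return the weather tibble with adjusted `t_min`, `t_avg`, `t_max`.
#' @examples
#' w <- tibble::tibble(date = as.Date("2000-05-01"), t_min = 0, t_avg = 5,
#'                     t_max = 10, precip = 0, snow_score = 0)
#' adjust_lapse_rate(w, phenology_config(elevation_diff = 200))
#' @export
adjust_lapse_rate <- function(weather, config = phenology_config()) {
  shift <- -config$lapse_rate * config$elevation_diff / 100
  dplyr::mutate(weather, dplyr::across(dplyr::all_of(c("t_min", "t_avg", "t_max")),
                                       ~ .x + shift))
}

# per-year scan helper: returns list of per-year data frames restricted to
# doy 1 .. 30 June, ordered by doy
spring_by_year <- function(weather) {
  w <- add_calendar(weather)
  w <- w[w$doy <= june30_doy(w$year), , drop = FALSE]
  split(w, w$year)
}

#' Date of frost-free nights
#'
#' The day the centred `ma_window`-day (default 7) moving average of daily
#' minimum temperature first rises above 0 degrees C, scanning 1 January to
#' 30 June of each year. If the earliest computable window is already
#' positive its centre day is returned; if no window mean is positive by 30
#' June the year is reported missing (`NA`).
#'
#' @inheritParams adjust_lapse_rate
#' @return tibble with columns `year`, `frost_free_doy` (day-of-year or NA).
#' @export
frost_free_date <- function(weather, config = phenology_config()) {
  half <- (config$ma_window - 1) / 2
  res <- purrr::map(spring_by_year(weather), function(w) {
    if (nrow(w) < config$ma_window) {
      abort(sprintf("year %d: fewer than %d spring days of t_min coverage",
                    w$year[1], config$ma_window))
    }
    if (any(diff(w$doy) != 1) || any(is.na(w$t_min))) {
      abort(sprintf("year %d: gap in daily t_min coverage inside the spring scan",
                    w$year[1]))
    }
    ma <- moving_average(w$t_min, config$ma_window)
    hit <- which(ma > 1e-9)   # strictly above 0 within numerical tolerance
    tibble::tibble(year = w$year[1],
                   frost_free_doy = if (length(hit)) w$doy[hit[1]] else NA_integer_)
  })
  dplyr::bind_rows(res)
}

#' Date of snow-free ground
#'
#' The earliest date of each year on which the reported snow-cover score is
#' at or below `snow_free_score` (default 0, i.e. less than 20 percent
#' cover on the 0--5 scale), scanning 1 January to 30 June.
#'
#' @inheritParams adjust_lapse_rate
#' @return tibble with columns `year`, `snow_free_doy` (day-of-year or NA).
#' @export
snow_free_date <- function(weather, config = phenology_config()) {
  check_columns(weather, "snow_score", "weather")
  res <- purrr::map(spring_by_year(weather), function(w) {
    if (all(is.na(w$snow_score))) {
      abort(sprintf("year %d: all snow scores missing in the spring scan",
                    w$year[1]))
    }
    hit <- which(!is.na(w$snow_score) & w$snow_score <= config$snow_free_score)
    tibble::tibble(year = w$year[1],
                   snow_free_doy = if (length(hit)) w$doy[hit[1]] else NA_integer_)
  })
  dplyr::bind_rows(res)
}

#' Cumulative growing degree days
#'
#' Accumulates `max(t_avg - gdd_base, 0)` per day from `gdd_start` (default
#' 1 January) within each year. The cumulative series is non-decreasing by
#' construction.
#'
#' @inheritParams adjust_lapse_rate
#' @return tibble with columns `date`, `year`, `doy`, `gdd`.
#' @export
gdd_accumulate <- function(weather, config = phenology_config()) {
  w <- add_calendar(weather)
  w <- w[w$doy >= config$gdd_start, , drop = FALSE]
  res <- purrr::map(split(w, w$year), function(x) {
    if (any(diff(x$doy) != 1) || any(is.na(x$t_avg))) {
      abort(sprintf("year %d: missing t_avg inside the accumulation range",
                    x$year[1]))
    }
    tibble::tibble(date = x$date, year = x$year, doy = x$doy,
                   gdd = cumsum(pmax(x$t_avg - config$gdd_base, 0)))
  })
  dplyr::bind_rows(res)
}

#' Onset of summer: date the GDD threshold is reached
#'
#' First day of each year on which cumulative growing degree days (base
#' `gdd_base`) reach `gdd_threshold` (default GDD5 = 200, matching completed
#' bilberry shoot growth in the study system); `NA` if never reached.
#'
#' @inheritParams adjust_lapse_rate
#' @return tibble with columns `year`, `gdd200_doy` (day-of-year or NA).
#' @export
gdd_onset_date <- function(weather, config = phenology_config()) {
  acc <- gdd_accumulate(weather, config)
  dplyr::summarise(
    dplyr::group_by(acc, .data$year),
    gdd200_doy = {
      hit <- which(.data$gdd >= config$gdd_threshold)
      if (length(hit)) .data$doy[hit[1]] else NA_integer_
    },
    .groups = "drop")
}

#' Per-year phenological onset dates
#'
#' Convenience wrapper joining [snow_free_date()], [frost_free_date()] and
#' [gdd_onset_date()] into one table of spring/summer onset indicators.
#'
#' @inheritParams adjust_lapse_rate
#' @return tibble `year`, `snow_free_doy`, `frost_free_doy`, `gdd200_doy`.
#' @export
phenology_onsets <- function(weather, config = phenology_config()) {
  out <- dplyr::full_join(snow_free_date(weather, config),
                          frost_free_date(weather, config), by = "year")
  dplyr::full_join(out, gdd_onset_date(weather, config), by = "year")
}

#' Mean temperature over day-of-year windows
#'
#' Computes the arithmetic mean of daily `t_min`, `t_avg` and/or `t_max`
#' over closed day-of-year windows, one row per window. Windows must lie
#' within a single calendar year; any missing day inside a window (absent
#' row or `NA` value) is an error reporting the number of gaps rather than
#' a silently biased mean.
#'
#' @param weather daily weather tibble.
#' @param windows tibble with columns `year`, `start_doy`, `end_doy` and any
#'   number of carried label columns (e.g. `window`, `species`).
#' @param vars which daily temperatures to average (default all three).
#' @return `windows` with one added mean column per requested variable,
#'   named `t_min_mean`, `t_avg_mean`, `t_max_mean`.
#' @export
window_means <- function(weather, windows,
                         vars = c("t_min", "t_avg", "t_max")) {
  check_columns(windows, c("year", "start_doy", "end_doy"), "windows")
  stopifnot(all(windows$end_doy >= windows$start_doy))
  if (any(windows$start_doy < 1)) {
    abort("window extends before day 1 of the year")
  }
  w <- add_calendar(weather)
  w <- w[order(w$date), , drop = FALSE]
  key <- w$year * 1000L + w$doy
  if (anyDuplicated(key)) abort("duplicate weather days")
  i0 <- match(windows$year * 1000L + windows$start_doy, key)
  i1 <- match(windows$year * 1000L + windows$end_doy, key)
  if (anyNA(i0) || anyNA(i1)) {
    abort(sprintf("%d window bound(s) fall outside the weather series",
                  sum(is.na(i0) | is.na(i1))))
  }
  len <- windows$end_doy - windows$start_doy + 1L
  covered <- i1 - i0 + 1L
  if (any(covered != len)) {
    abort(sprintf("weather series has day gaps inside %d window(s)",
                  sum(covered != len)))
  }
  out <- windows
  for (v in vars) {
    x <- w[[v]]
    csum <- c(0, cumsum(ifelse(is.na(x), 0, x)))
    cna <- c(0, cumsum(is.na(x)))
    ngap <- cna[i1 + 1L] - cna[i0]
    if (any(ngap > 0)) {
      abort(sprintf("%s missing on %d day(s) inside %d window(s)",
                    v, sum(ngap), sum(ngap > 0)))
    }
    out[[paste0(v, "_mean")]] <- (csum[i1 + 1L] - csum[i0]) / len
  }
  out
}

#' Mean temperature over a single window
#'
#' Scalar convenience form of [window_means()] for one year and one closed
#' day-of-year interval.
#'
#' @inheritParams window_means
#' @param year calendar year of the window.
#' @param start_doy,end_doy closed day-of-year bounds.
#' @param which one of `"min"`, `"avg"`, `"max"`.
#' @return a single numeric mean.
#' @export
window_mean <- function(weather, year, start_doy, end_doy, which = "avg") {
  which <- match.arg(which, c("min", "avg", "max"))
  v <- paste0("t_", which)
  res <- window_means(weather,
                      tibble::tibble(year = year, start_doy = start_doy,
                                     end_doy = end_doy),
                      vars = v)
  res[[paste0(v, "_mean")]]
}

#' Monthly temperature means
#'
#' Per year x month means of the daily temperatures, for the breeding-season
#' months by default (April--June). Months with any missing day raise an
#' error, matching the strict window policy.
#'
#' @inheritParams adjust_lapse_rate
#' @param months integer months to summarise (default `4:6`).
#' @return tibble `year`, `month`, `t_min_mean`, `t_avg_mean`, `t_max_mean`.
#' @export
monthly_means <- function(weather, months = 4:6) {
  w <- add_calendar(weather)
  grid <- dplyr::distinct(tibble::tibble(
    year = w$year, month = as.integer(format(w$date, "%m"))))
  grid <- grid[grid$month %in% months, , drop = FALSE]
  grid$start_doy <- day_of_year(as.Date(sprintf("%d-%02d-01", grid$year, grid$month)))
  last <- ifelse(grid$month == 12,
                 as.Date(sprintf("%d-12-31", grid$year)),
                 as.Date(sprintf("%d-%02d-01", grid$year, grid$month + 1L)) - 1)
  grid$end_doy <- day_of_year(as.Date(last, origin = "1970-01-01"))
  out <- window_means(w, grid)
  dplyr::arrange(out[, c("year", "month", "t_min_mean", "t_avg_mean", "t_max_mean")],
                 .data$year, .data$month)
}

#' Successive breeding-season periods
#'
#' Builds `n` consecutive `period_days`-day windows tiling the breeding
#' season from 1 April of each year (the default 13 weekly periods tile
#' 1 April -- 30 June exactly: 13 x 7 = 91 days).
#'
#' @param years integer vector of years.
#' @param n number of successive periods (default 13).
#' @param period_days length of each period in days (default 7).
#' @return tibble `year`, `period`, `start_doy`, `end_doy`.
#' @export
season_periods <- function(years, n = 13, period_days = 7) {
  grid <- tidyr::expand_grid(year = unique(as.integer(years)),
                             period = seq_len(n))
  start <- april1_doy(grid$year) + (grid$period - 1L) * period_days
  dplyr::mutate(grid, start_doy = start,
                end_doy = start + period_days - 1L)
}
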