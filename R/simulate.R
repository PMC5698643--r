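# Synthetic study-system generator: daily weather with differential monthly
# warming, cyclic rodents coupled to summer temperature, fox lagged one year
# behind rodents, capercaillie mating peaks with a weak advance, and August
# brood-survey records whose brood frequency and brood size respond to the
# pre- and post-hatch temperature windows. Every stage is reproducible from
# a single seed so the full pipeline can be exercised and its estimators
# checked at desk scale.

default_monthly_slopes <- function() {
  # degrees C per year by calendar month; April/May/June carry the study
  # system's printed warming slopes, other months a modest uniform warming
  s <- tibble::tibble(month = 1:12,
                      t_min = 0.03, t_avg = 0.03, t_max = 0.03)
  s[4, 2:4] <- list(0.050, 0.069, 0.101)
  s[5, 2:4] <- list(0.052, 0.019, 0.012)
  s[6, 2:4] <- list(0.047, 0.022, 0.024)
  s
}

#' Simulation configuration for the synthetic grouse study
#'
#' Bundles every generator parameter with defaults emulating the study
#' system: a 38-year series starting 1979; a seasonal temperature sinusoid
#' with AR(1) daily noise and month-specific warming strongest in April; a
#' degree-day snow-pack model; 3--4-year rodent cycles coupled to same-year
#' summer temperature with fox following rodents at lag 1; a weak advance
#' of the capercaillie mating peak; and a breeding model in which brood
#' frequency responds to pre-hatch minimum temperature (capercaillie only)
#' and brood size to post-hatch minimum temperature (both species).
#' Demographic effect sizes are given on the linear scale of the pipeline's
#' window regressions (slope of the index per degree C) and converted
#' internally to the logit/log link scales at the baseline index values;
#' the match is first-order, not exact.
#'
#' @param n_years,start_year length and first year of the series.
#' @param monthly_slopes tibble `month`, `t_min`, `t_avg`, `t_max` of
#'   warming slopes (degrees C per year).
#' @param weather list: `site_mean`, `amplitude`, `peak_doy` of the seasonal
#'   sinusoid (degrees C, days); `min_offset`, `max_offset` diurnal offsets
#'   of daily minimum/maximum around the mean; `ar_phi`, `ar_sd` AR(1)
#'   coefficient and innovation sd of the shared daily noise;
#'   `month_anom_sd` sd of the shared month-level weather anomaly (one
#'   draw per year x month, emulating persistent circulation regimes and
#'   giving window means their realistic interannual spread); `extra_sd`
#'   independent per-variable noise; `wet_prob`, `precip_shape`,
#'   `precip_mean` precipitation model; `swe_init`, `melt_factor`,
#'   `accum_tmax` snow-pack model (mm water equivalent, mm per degree-day,
#'   accumulation temperature ceiling).
#' @param rodent list: `period` (years), `amplitude`, `base`,
#'   `temp_coupling` (index units per degree C of same-year June--August
#'   mean), `ref_summer` (degrees C), `noise_sd`.
#' @param fox list: `base`, `lag_coupling` (index units per lag-1 rodent
#'   unit), `noise_sd`.
#' @param mating list: `baseline_doy`, `trend` (days per year),
#'   `onset_coupling` (days per day of detrended frost-free anomaly),
#'   `noise_sd` (days).
#' @param breeding list of per-species named vectors / scalars:
#'   `n_females` mean females encountered per year; `brood_p0` baseline
#'   brood probability; `bf_temp_effect` linear-scale slope of brood
#'   frequency on pre-hatch (8-week) minimum temperature; `bf_rodent_effect`
#'   linear-scale slope on the rodent index; `ref_t_pre` reference pre-hatch
#'   temperatures; `brood_size_mean` baseline chicks per brood;
#'   `bs_temp_effect` linear-scale slope of brood size on post-hatch
#'   (4-week) minimum temperature; `clutch` hatched clutch size (chicks in
#'   a brood are the binomial survivors of the clutch, floored at one --
#'   August surveys only see broods with at least one surviving chick);
#'   `ref_t_post`; `mismatch_gamma` log-scale quadratic penalty of expected
#'   brood size per squared day of hatch-date offset from the GDD5 = 200
#'   date (0 = effects act through temperature only).
#' @param survey list: `n_blocks` available sampling blocks,
#'   `blocks_sampled` blocks visited per species-year, `hours_min`,
#'   `hours_max` effort range per block, `other_birds_mean` expected
#'   males/unclassified per species-year.
#' @param offsets a [breeding_offsets()] object.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_years = 38, start_year = 1979,
                       monthly_slopes = default_monthly_slopes(),
                       weather = list(), rodent = list(), fox = list(),
                       mating = list(), breeding = list(), survey = list(),
                       offsets = breeding_offsets()) {
  merge_defaults <- function(user, defaults) {
    utils::modifyList(defaults, as.list(user))
  }
  cfg <- list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    monthly_slopes = tibble::as_tibble(monthly_slopes),
    weather = merge_defaults(weather, list(
      site_mean = 2.5, amplitude = 13.7, peak_doy = 201,
      min_offset = -4.5, max_offset = 5.5,
      ar_phi = 0.6, ar_sd = 1.6, month_anom_sd = 1.2, extra_sd = 0.4,
      wet_prob = 0.4, precip_shape = 0.7, precip_mean = 3.5,
      swe_init = 40, melt_factor = 5, accum_tmax = 0.5)),
    rodent = merge_defaults(rodent, list(
      period = 3.5, amplitude = 2.2, base = 3,
      temp_coupling = 0.22, ref_summer = 13, noise_sd = 0.5)),
    fox = merge_defaults(fox, list(
      base = 1, lag_coupling = 0.078, noise_sd = 0.15)),
    mating = merge_defaults(mating, list(
      baseline_doy = 121, trend = -0.12, onset_coupling = 0.15,
      noise_sd = 2)),
    breeding = merge_defaults(breeding, list(
      n_females = c(capercaillie = 18, black_grouse = 22),
      brood_p0 = c(capercaillie = 0.45, black_grouse = 0.55),
      bf_temp_effect = c(capercaillie = 0.049, black_grouse = 0),
      bf_rodent_effect = c(capercaillie = 0.03, black_grouse = 0.03),
      ref_t_pre = c(capercaillie = 3, black_grouse = 4),
      brood_size_mean = 4.3,
      bs_temp_effect = c(capercaillie = 0.136, black_grouse = 0.138),
      clutch = 8,
      ref_t_post = 9,
      mismatch_gamma = 0)),
    survey = merge_defaults(survey, list(
      n_blocks = 25, blocks_sampled = 10, hours_min = 8, hours_max = 15,
      other_birds_mean = 10)),
    offsets = offsets)
  stopifnot(cfg$n_years >= 2, nrow(cfg$monthly_slopes) == 12,
            cfg$weather$ar_sd >= 0, cfg$rodent$period > 0)
  structure(cfg, class = "sim_config")
}

sim_years <- function(config) seq(config$start_year, length.out = config$n_years)

#' Simulate a daily weather series
#'
#' Daily minimum/average/maximum temperatures are a seasonal sinusoid plus
#' month-specific linear warming plus shared AR(1) daily noise, a shared
#' month-level anomaly and small independent per-variable noise; the ordering `t_min <= t_avg <= t_max`
#' is enforced by construction. Precipitation is a wet-day gamma process and
#' snow cover follows a degree-day snow-pack whose water equivalent is
#' mapped to the ordinal 0--5 score.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return a daily weather tibble (`date`, `t_min`, `t_avg`, `t_max`,
#'   `precip`, `snow_score`) spanning the configured years.
#' @export
simulate_weather <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cw <- config$weather
  y0 <- config$start_year
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y0 + config$n_years - 1)), by = "day")
  n <- length(dates)
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  year <- lt$year + 1900L
  month <- lt$mon + 1L
  t <- year - y0
  base <- cw$site_mean + cw$amplitude * cos(2 * pi * (doy - cw$peak_doy) / 365.25)
  e <- ar1_noise(n, cw$ar_phi, cw$ar_sd)
  # one shared anomaly per year x month: persistent weather regimes that
  # dominate the interannual spread of monthly/window means
  ym <- (year - y0) * 12L + month
  e <- e + rnorm(max(ym), 0, cw$month_anom_sd)[ym]
  sl <- config$monthly_slopes
  mk <- function(var, offset) {
    base + offset + sl[[var]][month] * t + e + rnorm(n, 0, cw$extra_sd)
  }
  t_avg <- mk("t_avg", 0)
  t_min <- pmin(mk("t_min", cw$min_offset), t_avg)
  t_max <- pmax(mk("t_max", cw$max_offset), t_avg)
  precip <- rbinom(n, 1, cw$wet_prob) *
    rgamma(n, shape = cw$precip_shape,
           rate = cw$precip_shape / cw$precip_mean)
  # degree-day snow-pack: accumulate precipitation on cold days, melt
  # proportionally to above-zero mean temperature
  swe <- numeric(n)
  s <- cw$swe_init
  for (i in seq_len(n)) {
    s <- s + (t_avg[i] <= cw$accum_tmax) * precip[i] -
      cw$melt_factor * max(t_avg[i], 0)
    if (s < 0) s <- 0
    swe[i] <- s
  }
  score <- findInterval(swe, c(1, 8, 15, 25, 40))
  tibble::tibble(date = dates, t_min = t_min, t_avg = t_avg, t_max = t_max,
                 precip = precip, snow_score = as.integer(score))
}

#' Simulate rodent and fox covariate series
#'
#' The small-rodent index is a sinusoidal 3--4 year cycle (random phase)
#' plus a linear coupling to the same-year June--August mean temperature
#' plus noise; the fox index follows the rodent index of the previous year.
#' Both are floored just above zero.
#'
#' @inheritParams simulate_weather
#' @param weather a simulated daily weather tibble (for the summer means).
#' @return tibble `year`, `rodent_index`, `fox_index`.
#' @export
simulate_covariates <- function(config = sim_config(), weather, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cr <- config$rodent
  cf <- config$fox
  summer <- summer_mean_temp(weather)
  stopifnot(all(summer$year == sim_years(config)))
  t <- seq_len(config$n_years) - 1
  phase <- runif(1, 0, 2 * pi)
  rodent <- cr$base + cr$amplitude * sin(2 * pi * t / cr$period + phase) +
    cr$temp_coupling * (summer$t_summer - cr$ref_summer) +
    rnorm(config$n_years, 0, cr$noise_sd)
  rodent <- pmax(rodent, 0.01)
  fox <- cf$base + cf$lag_coupling * dplyr::lag(rodent, default = rodent[1]) +
    rnorm(config$n_years, 0, cf$noise_sd)
  tibble::tibble(year = summer$year, rodent_index = rodent,
                 fox_index = pmax(fox, 0.01))
}

#' Simulate capercaillie mating-peak dates
#'
#' Mating day = baseline + configured yearly trend + a weak coupling to the
#' detrended frost-free-date anomaly (so a cold late spring delays mating
#' without altering the configured long-term trend) + noise, rounded to
#' whole days.
#'
#' @inheritParams simulate_weather
#' @param onsets optional per-year onset table (from [phenology_onsets()])
#'   supplying `frost_free_doy`; without it the coupling term is omitted.
#' @return tibble `year`, `species = "capercaillie"`, `mating_doy`.
#' @export
simulate_mating_dates <- function(config = sim_config(), onsets = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cm <- config$mating
  years <- sim_years(config)
  t <- seq_along(years) - 1
  anom <- 0
  if (!is.null(onsets) && all(!is.na(onsets$frost_free_doy))) {
    ff <- onsets$frost_free_doy[match(years, onsets$year)]
    anom <- residuals(lm(ff ~ years))
  }
  doy <- cm$baseline_doy + cm$trend * t + cm$onset_coupling * anom +
    rnorm(length(years), 0, cm$noise_sd)
  tibble::tibble(year = years, species = "capercaillie",
                 mating_doy = round(doy))
}

#' Simulate August brood-survey records
#'
#' For each species-year: the number of females encountered is Poisson;
#' each female has a brood with probability given by a logit link whose
#' slope on the 8-week pre-hatch minimum temperature and on the rodent
#' index is scale-matched to the configured linear effects; brood sizes are
#' zero-truncated Poisson with a log-link slope on the 4-week post-hatch
#' minimum temperature (and, optionally, a quadratic penalty on the
#' hatch-date offset from the GDD threshold date). Birds are spread over
#' sampled blocks with uniform effort hours.
#'
#' @inheritParams simulate_covariates
#' @param covariates tibble from [simulate_covariates()].
#' @param phenology species-year phenology from
#'   [breeding_phenology_table()].
#' @param onsets optional onset table; required when the configured
#'   `mismatch_gamma` is non-zero.
#' @return survey tibble `year`, `species`, `block`, `hours`,
#'   `females_no_brood`, `brood_chicks` (semicolon string), `other_birds`.
#' @export
simulate_breeding <- function(config = sim_config(), weather, covariates,
                              phenology, onsets = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cb <- config$breeding
  cs <- config$survey
  win <- build_windows(phenology)
  win <- win[win$window %in% c("pre8", "post4"), , drop = FALSE]
  wm <- window_means(weather, win, vars = "t_min")
  temps <- tidyr::pivot_wider(
    wm[, c("year", "species", "window", "t_min_mean")],
    names_from = "window", values_from = "t_min_mean")
  d <- dplyr::left_join(temps, covariates[, c("year", "rodent_index")],
                        by = "year")
  d <- dplyr::left_join(
    d, phenology[, c("year", "species", "hatch_doy")],
    by = c("year", "species"))
  if (cb$mismatch_gamma != 0) {
    if (is.null(onsets)) abort("onsets required when mismatch_gamma != 0")
    d <- dplyr::left_join(d, onsets[, c("year", "gdd200_doy")], by = "year")
    d$offset <- d$hatch_doy - d$gdd200_doy
  } else {
    d$offset <- 0
  }
  sp <- d$species
  p_brood <- brood_probability(config, sp, d$pre8, d$rodent_index)
  m <- expected_brood_size(config, sp, d$post4, d$offset)
  q <- pmin(pmax((m - 1) / (cb$clutch - 1), 0.02), 0.98)
  rows <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    n_f <- rpois(1, cb$n_females[sp[i]])
    n_b <- rbinom(1, n_f, p_brood[i])
    chicks <- 1L + rbinom(n_b, cb$clutch - 1L, q[i])
    blocks <- sort(sample.int(cs$n_blocks, min(cs$blocks_sampled, cs$n_blocks)))
    assign_b <- if (n_f > 0) sample(blocks, n_f, replace = TRUE) else integer()
    brooded <- head(assign_b, n_b)     # females are exchangeable
    lone <- tail(assign_b, n_f - n_b)
    rows[[i]] <- tibble::tibble(
      year = d$year[i], species = sp[i], block = blocks,
      hours = round(runif(length(blocks), cs$hours_min, cs$hours_max), 1),
      females_no_brood = as.integer(tabulate(match(lone, blocks),
                                             length(blocks))),
      brood_chicks = vapply(blocks, function(b) {
        paste(chicks[brooded == b], collapse = ";")
      }, character(1)),
      other_birds = rpois(length(blocks),
                          cs$other_birds_mean / length(blocks)))
  }
  dplyr::bind_rows(rows)
}


#' Generator link functions
#'
#' The exact per-year expectations the breeding generator draws from,
#' exposed so large-sample behaviour can be checked against them.
#' `brood_probability` is the logit-link brood probability given the
#' 8-week pre-hatch minimum temperature and the rodent index (linear-scale
#' configured effects converted to the logit scale at the baseline).
#' `expected_brood_size` is the log-link expected chicks per brood given
#' the 4-week post-hatch minimum temperature and, optionally, the
#' hatch-date offset.
#'
#' @inheritParams simulate_weather
#' @param species character vector of species names.
#' @param t_pre,t_post window minimum-temperature means (degrees C).
#' @param rodent rodent index values.
#' @param offset hatch-date offset from the GDD threshold date (days).
#' @return numeric vector of probabilities / expected brood sizes.
#' @export
brood_probability <- function(config, species, t_pre, rodent) {
  cb <- config$breeding
  p0 <- cb$brood_p0[species]
  # scale-match: linear-scale effects converted to the logit link
  stats::plogis(stats::qlogis(p0) +
    (cb$bf_temp_effect[species] / (p0 * (1 - p0))) * (t_pre - cb$ref_t_pre[species]) +
    (cb$bf_rodent_effect[species] / (p0 * (1 - p0))) * (rodent - config$rodent$base))
}

#' @rdname brood_probability
#' @export
expected_brood_size <- function(config, species, t_post, offset = 0) {
  cb <- config$breeding
  cb$brood_size_mean *
    exp((cb$bs_temp_effect[species] / cb$brood_size_mean) * (t_post - cb$ref_t_post) -
          cb$mismatch_gamma * offset^2)
}

#' Simulate a complete study bundle
#'
#' Runs the whole generator under one seed: weather, phenological onsets,
#' covariates, mating dates, the derived two-species phenology table, and
#' the survey records. This is the entry point both for pipeline tests and
#' for writing fixture bundles with [write_fixture()].
#'
#' @inheritParams simulate_weather
#' @return a list of class `grouse_study` with elements `weather`,
#'   `onsets`, `covariates`, `mating`, `phenology`, `survey`, `config`,
#'   `seed`.
#' @examples
#' \donttest{
#' study <- sim_study(seed = 1)
#' demographic_indices(study$survey)
#' }
#' @export
sim_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weather <- simulate_weather(config)
  onsets <- phenology_onsets(weather)
  covariates <- simulate_covariates(config, weather)
  mating <- simulate_mating_dates(config, onsets)
  phenology <- breeding_phenology_table(mating, config$offsets)
  survey <- simulate_breeding(config, weather, covariates, phenology, onsets)
  structure(list(weather = weather, onsets = onsets, covariates = covariates,
                 mating = mating, phenology = phenology, survey = survey,
                 config = config, seed = seed),
            class = "grouse_study")
}

#' @export
print.grouse_study <- function(x, ...) {
  cat(sprintf("Synthetic grouse study: %d years from %d (seed %s)\n",
              x$config$n_years, x$config$start_year,
              x$seed %||% "unset"))
  cat(sprintf("  %d weather days, %d survey records, %d phenology rows\n",
              nrow(x$weather), nrow(x$survey), nrow(x$phenology)))
  invisible(x)
}
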