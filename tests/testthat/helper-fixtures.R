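# In-code fixtures: small daily weather series and survey tables built
# programmatically so tests carry no data files.

# full-year (or multi-year) daily weather with recyclable or
# function-of-doy temperature specs
make_weather <- function(years = 2000, t_avg = 10, t_min = NULL, t_max = NULL,
                         precip = 0, snow_score = 0L) {
  years <- sort(unique(years))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  val <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.function(x)) x(doy) else rep_len(x, length(dates))
  }
  t_avg <- val(t_avg, NULL)
  tibble::tibble(
    date = dates,
    t_avg = t_avg,
    t_min = val(t_min, t_avg - 5),
    t_max = val(t_max, t_avg + 5),
    precip = val(precip, 0),
    snow_score = as.integer(val(snow_score, 0L)))[,
      c("date", "t_min", "t_avg", "t_max", "precip", "snow_score")]
}

# one survey record row
survey_row <- function(year, species = "capercaillie", block = 1, hours = 10,
                       females_no_brood = 0, brood_chicks = "",
                       other_birds = 0) {
  tibble::tibble(year = year, species = species, block = block, hours = hours,
                 females_no_brood = females_no_brood,
                 brood_chicks = brood_chicks, other_birds = other_birds)
}

# random survey table for property tests
random_survey <- function(seed, n_years = 6) {
  set.seed(seed)
  rows <- list()
  for (y in seq_len(n_years) + 2000) {
    for (sp in c("capercaillie", "black_grouse")) {
      n_blocks <- sample(2:4, 1)
      for (b in seq_len(n_blocks)) {
        nb <- rpois(1, 2)
        rows[[length(rows) + 1]] <- survey_row(
          y, sp, b, hours = round(runif(1, 5, 15), 1),
          females_no_brood = rpois(1, 3),
          brood_chicks = paste(sample(1:8, nb, replace = TRUE), collapse = ";"),
          other_birds = rpois(1, 2))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# tiny phenology table for window tests
make_phenology <- function(years = 2000, mating = 118,
                           offsets = breeding_offsets()) {
  cap <- derive_capercaillie_dates(
    tibble::tibble(year = years, mating_doy = mating), offsets)
  dplyr::bind_rows(cap, derive_black_grouse_dates(cap, offsets))
}
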