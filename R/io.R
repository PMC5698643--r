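# Readers/writers for the four plain-text input formats and fixture
# bundles. All readers validate the expected schema; empty fields are
# missing values.

#' Read a daily weather CSV
#'
#' Expected header: `date,t_min,t_avg,t_max,precip,snow_score` with
#' ISO-8601 dates; empty fields are missing. The series is validated with
#' [validate_weather()].
#'
#' @param path file path.
#' @return a daily weather tibble.
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), t_min = readr::col_double(),
    t_avg = readr::col_double(), t_max = readr::col_double(),
    precip = readr::col_double(), snow_score = readr::col_integer()))
  validate_weather(w)
  w
}

#' Read an August survey CSV
#'
#' Expected header: `year,species,block,hours,females_no_brood,brood_chicks`
#' (optionally `other_birds`); `brood_chicks` is a semicolon-separated list
#' of chick counts, empty for none.
#'
#' @param path file path.
#' @return a survey tibble.
#' @export
read_survey_csv <- function(path) {
  s <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), species = readr::col_character(),
    block = readr::col_integer(), hours = readr::col_double(),
    females_no_brood = readr::col_integer(),
    brood_chicks = readr::col_character(),
    .default = readr::col_integer()))
  s$brood_chicks[is.na(s$brood_chicks)] <- ""
  check_columns(s, c("year", "species", "block", "hours",
                     "females_no_brood", "brood_chicks"), "survey CSV")
  s
}

#' Read an annual covariate CSV (`year,rodent_index,fox_index`)
#' @param path file path.
#' @return a covariates tibble.
#' @export
read_covariates_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), rodent_index = readr::col_double(),
    fox_index = readr::col_double()))
}

#' Read a mating-date CSV (`year,species,mating_doy`)
#' @param path file path.
#' @return a mating tibble.
#' @export
read_mating_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), species = readr::col_character(),
    mating_doy = readr::col_double()))
}

#' Write a simulated study to a fixture directory
#'
#' Emits the four pipeline input CSVs (`weather.csv`, `survey.csv`,
#' `covariates.csv`, `mating.csv`) plus `manifest.yaml` echoing the full
#' generating configuration and seed, so a bundle is self-describing and
#' reproducible.
#'
#' @param study a `grouse_study` from [sim_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "grouse_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$weather, file.path(dir, "weather.csv"))
  readr::write_csv(study$survey, file.path(dir, "survey.csv"))
  readr::write_csv(study$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(study$mating, file.path(dir, "mating.csv"))
  manifest <- list(seed = study$seed, config = config_to_list(study$config))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

# flatten a sim_config into plain lists for yaml
config_to_list <- function(config) {
  list(n_years = config$n_years, start_year = config$start_year,
       monthly_slopes = lapply(as.list(config$monthly_slopes), as.numeric),
       weather = config$weather, rodent = config$rodent, fox = config$fox,
       mating = config$mating,
       breeding = lapply(config$breeding, function(x) as.list(x)),
       survey = config$survey,
       offsets = unclass(config$offsets))
}

# rebuild a sim_config from a manifest list
config_from_list <- function(lst) {
  named_vec <- function(x) if (is.list(x)) unlist(x) else x
  off <- lst$offsets
  sim_config(
    n_years = lst$n_years, start_year = lst$start_year,
    monthly_slopes = tibble::as_tibble(lst$monthly_slopes),
    weather = lst$weather, rodent = lst$rodent, fox = lst$fox,
    mating = lst$mating,
    breeding = lapply(lst$breeding, named_vec),
    survey = lst$survey,
    offsets = breeding_offsets(
      mating_lag_bg = off$mating_lag_bg,
      incubation_lag_bg = off$incubation_lag_bg,
      hatch_lag_bg = off$hatch_lag_bg,
      mating_to_hatch_cap = off$mating_to_hatch_cap,
      incubation_length_cap = off$incubation_length_cap))
}

#' Read a fixture directory back into memory
#'
#' Loads the four CSVs and the manifest written by [write_fixture()],
#' rebuilding the [sim_config()] from the manifest echo.
#'
#' @param dir fixture directory.
#' @return list with `weather`, `survey`, `covariates`, `mating`, `config`,
#'   `seed`.
#' @export
read_fixture <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  list(weather = read_weather_csv(file.path(dir, "weather.csv")),
       survey = read_survey_csv(file.path(dir, "survey.csv")),
       covariates = read_covariates_csv(file.path(dir, "covariates.csv")),
       mating = read_mating_csv(file.path(dir, "mating.csv")),
       config = config_from_list(manifest$config),
       seed = manifest$seed)
}
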