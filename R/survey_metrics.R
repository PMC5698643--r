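# August pointing-dog survey records -> encounter rates and the three
# demographic indices (breeding success, brood frequency, brood size).
# Records are pooled across sampling blocks before ratios are formed
# (ratio of sums, not mean of ratios), giving one annual value per species.

#' Parse semicolon-separated brood chick counts
#'
#' Survey CSVs store each record's broods as a semicolon-separated list of
#' chick counts (empty string = no broods). This converts that column to a
#' list of integer vectors.
#'
#' @param x character vector like `"3;4;2"`, `""`, or `NA`.
#' @return list of integer vectors (length-0 for no broods).
#' @export
parse_broods <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer())
    v <- as.integer(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
    if (anyNA(v) || any(v < 1)) {
      abort("every brood must have a positive integer chick count")
    }
    v
  })
}

# normalise a survey tibble: ensure broods list-column and per-record tallies
prepare_survey <- function(survey) {
  check_columns(survey, c("year", "species", "hours", "females_no_brood"),
                "survey")
  if (!"brood_chicks" %in% names(survey)) abort("survey needs a brood_chicks column")
  broods <- if (is.list(survey$brood_chicks)) survey$brood_chicks
            else parse_broods(survey$brood_chicks)
  if (any(survey$hours <= 0)) abort("sampling_hours must be positive")
  if (any(survey$females_no_brood < 0)) abort("counts must be non-negative")
  dplyr::mutate(survey,
                broods = broods,
                n_broods = lengths(broods),
                n_chicks = purrr::map_int(broods, ~ as.integer(sum(.x))),
                other_birds = if ("other_birds" %in% names(survey))
                  survey$other_birds else 0L)
}

#' Encounter rate in birds per 10 hours
#'
#' Pools records within species-year (sum of birds over sum of effort) and
#' expresses abundance as birds per 10 h of sampling. Birds counted are
#' lone females, brooded females, their chicks, and any `other_birds`
#' (males/unclassified).
#'
#' @param survey tibble `year`, `species`, `block`, `hours`,
#'   `females_no_brood`, `brood_chicks` (semicolon string or list-column),
#'   optionally `other_birds`.
#' @return tibble `year`, `species`, `n_birds`, `hours`, `rate_per_10h`.
#' @export
encounter_rate <- function(survey) {
  s <- prepare_survey(survey)
  out <- dplyr::summarise(
    dplyr::group_by(s, .data$year, .data$species),
    n_birds = sum(.data$females_no_brood + .data$n_broods + .data$n_chicks +
                    .data$other_birds),
    hours = sum(.data$hours),
    .groups = "drop")
  dplyr::mutate(out, rate_per_10h = 10 * .data$n_birds / .data$hours)
}

#' Demographic indices per species-year
#'
#' Aggregates survey records into the three August demographic indices:
#' breeding success (chicks per female), brood frequency (proportion of
#' females with at least one chick; reflects mainly egg-stage loss), and
#' brood size (chicks per brooded female; reflects mainly post-hatch chick
#' loss). Females are lone females plus brooded females; non-breeders are
#' indistinguishable from failed breeders in August counts. The identity
#' `breeding_success = brood_frequency * brood_size` holds exactly whenever
#' at least one brood was seen.
#'
#' @inheritParams encounter_rate
#' @param complete_years if `TRUE` (default), fill species-years without
#'   observations inside the spanned year range with `NA` index rows.
#' @return tibble `year`, `species`, `breeding_success`, `brood_frequency`,
#'   `brood_size`, `n_females`, `n_broods`, `n_chicks`, sorted by species
#'   and year.
#' @examples
#' s <- tibble::tibble(year = 2000, species = "capercaillie", block = 1,
#'                     hours = 10, females_no_brood = 4,
#'                     brood_chicks = "3;3;4;4;4")
#' demographic_indices(s)
#' @export
demographic_indices <- function(survey, complete_years = TRUE) {
  s <- prepare_survey(survey)
  out <- dplyr::summarise(
    dplyr::group_by(s, .data$year, .data$species),
    n_broods = sum(.data$n_broods),
    n_chicks = sum(.data$n_chicks),
    n_females = sum(.data$females_no_brood) + sum(.data$n_broods),
    .groups = "drop")
  if (any(out$n_females < 1)) {
    bad <- out[out$n_females < 1, ]
    warn(sprintf("no females observed for %d species-year(s); indices set NA",
                 nrow(bad)))
  }
  out <- dplyr::mutate(out,
    breeding_success = ifelse(.data$n_females > 0,
                              .data$n_chicks / .data$n_females, NA_real_),
    brood_frequency = ifelse(.data$n_females > 0,
                             .data$n_broods / .data$n_females, NA_real_),
    brood_size = ifelse(.data$n_broods > 0,
                        .data$n_chicks / .data$n_broods, NA_real_))
  if (complete_years) {
    out <- tidyr::complete(out, year = tidyr::full_seq(.data$year, 1),
                           species = unique(out$species))
  }
  cols <- c("year", "species", "breeding_success", "brood_frequency",
            "brood_size", "n_females", "n_broods", "n_chicks")
  dplyr::arrange(out[, cols], .data$species, .data$year)
}
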