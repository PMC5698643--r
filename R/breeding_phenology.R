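# Breeding phenology: capercaillie mating peaks anchor incubation-start and
# hatch dates; black grouse dates follow at fixed lags; the four
# breeding-season analysis windows are realized per species-year.

check_phenology_invariants <- function(ph) {
  bad <- !(ph$mating_doy < ph$incubation_start_doy &
             ph$incubation_start_doy < ph$hatch_doy)
  if (any(bad)) {
    abort(sprintf(
      "mating < incubation start < hatch violated for %d record(s) (first: year %s, %s)",
      sum(bad), ph$year[which(bad)[1]], ph$species[which(bad)[1]]))
  }
  invisible(ph)
}

#' Derive capercaillie breeding dates from mating peaks
#'
#' Hatching is the mating peak plus the mating-to-hatch interval; incubation
#' starts one incubation length before hatching (the remainder is the laying
#' period). Shifting the mating date by k days shifts both derived dates by
#' k.
#'
#' @param mating tibble with columns `year` and `mating_doy` (capercaillie
#'   mating-peak day-of-year).
#' @param offsets a [breeding_offsets()] object.
#' @return tibble `year`, `species`, `mating_doy`, `incubation_start_doy`,
#'   `hatch_doy`.
#' @examples
#' derive_capercaillie_dates(tibble::tibble(year = 2000, mating_doy = 118))
#' @export
derive_capercaillie_dates <- function(mating, offsets = breeding_offsets()) {
  check_columns(mating, c("year", "mating_doy"), "mating")
  ph <- tibble::tibble(
    year = mating$year,
    species = "capercaillie",
    mating_doy = mating$mating_doy,
    hatch_doy = mating$mating_doy + offsets$mating_to_hatch_cap,
    incubation_start_doy = mating$mating_doy + offsets$mating_to_hatch_cap -
      offsets$incubation_length_cap)
  ph <- ph[, c("year", "species", "mating_doy", "incubation_start_doy", "hatch_doy")]
  check_phenology_invariants(ph)
}

#' Derive black grouse dates from capercaillie dates
#'
#' Applies the interspecific lags: black grouse mate, start incubating and
#' hatch 5, 8 and 6 days after capercaillie by default.
#'
#' @param capercaillie a capercaillie phenology tibble from
#'   [derive_capercaillie_dates()].
#' @inheritParams derive_capercaillie_dates
#' @return tibble with the same columns, `species = "black_grouse"`.
#' @export
derive_black_grouse_dates <- function(capercaillie,
                                      offsets = breeding_offsets()) {
  check_columns(capercaillie,
                c("year", "mating_doy", "incubation_start_doy", "hatch_doy"),
                "capercaillie phenology")
  if (!all(capercaillie$species == "capercaillie")) {
    abort("input must be capercaillie records")
  }
  ph <- dplyr::mutate(capercaillie,
                      species = "black_grouse",
                      mating_doy = .data$mating_doy + offsets$mating_lag_bg,
                      incubation_start_doy =
                        .data$incubation_start_doy + offsets$incubation_lag_bg,
                      hatch_doy = .data$hatch_doy + offsets$hatch_lag_bg)
  check_phenology_invariants(ph)
}

#' Per-year breeding phenology for both species, with imputation
#'
#' Builds the complete species-year phenology table from observed
#' capercaillie mating peaks. Years missing an observation inside the
#' spanned range are imputed from the ordinary linear trend of the observed
#' dates (rounded to whole days) and flagged, so downstream inference can
#' exclude them.
#'
#' @param mating tibble `year`, `mating_doy`; `NA` or absent years are
#'   imputed. At least two observed years are required to fit the trend.
#' @inheritParams derive_capercaillie_dates
#' @return tibble `year`, `species`, `mating_doy`, `incubation_start_doy`,
#'   `hatch_doy`, `imputed` for both species.
#' @export
breeding_phenology_table <- function(mating, offsets = breeding_offsets()) {
  check_columns(mating, c("year", "mating_doy"), "mating")
  obs <- mating[!is.na(mating$mating_doy), , drop = FALSE]
  if (nrow(obs) < 2) abort("need at least 2 observed mating years")
  years <- seq(min(mating$year), max(mating$year))
  full <- tibble::tibble(year = years)
  full <- dplyr::left_join(full, mating[, c("year", "mating_doy")], by = "year")
  full$imputed <- is.na(full$mating_doy)
  if (any(full$imputed)) {
    fit <- lm(mating_doy ~ year, data = obs)
    full$mating_doy[full$imputed] <-
      round(predict(fit, newdata = full[full$imputed, ]))
  }
  cap <- derive_capercaillie_dates(full, offsets)
  cap$imputed <- full$imputed
  bg <- derive_black_grouse_dates(cap[, names(cap) != "imputed"], offsets)
  bg$imputed <- full$imputed
  dplyr::arrange(dplyr::bind_rows(cap, bg), .data$year, .data$species)
}

#' Realize the four breeding-season analysis windows
#'
#' For each species-year phenology record, materializes the closed
#' day-of-year ranges used in the climate-window regressions:
#' `pre8` = 8 weeks pre-hatching, split into `pre_inc4` = 4 weeks
#' pre-incubation and `inc` = incubation (ending the day before hatch),
#' plus `post4` = 4 weeks post-hatching.
#'
#' @param phenology tibble with `year`, `species`, `incubation_start_doy`,
#'   `hatch_doy` (other columns carried through are dropped).
#' @return tibble `year`, `species`, `window`, `start_doy`, `end_doy` with
#'   `window` in `c("pre8", "pre_inc4", "inc", "post4")`.
#' @export
build_windows <- function(phenology) {
  check_columns(phenology, c("year", "species", "incubation_start_doy", "hatch_doy"),
                "phenology")
  check_phenology_invariants(phenology)
  w <- tidyr::expand_grid(
    phenology[, c("year", "species", "incubation_start_doy", "hatch_doy")],
    window = c("pre8", "pre_inc4", "inc", "post4"))
  w <- dplyr::mutate(w,
    start_doy = dplyr::case_match(.data$window,
      "pre8" ~ .data$hatch_doy - 56L,
      "pre_inc4" ~ .data$incubation_start_doy - 28L,
      "inc" ~ .data$incubation_start_doy,
      "post4" ~ .data$hatch_doy),
    end_doy = dplyr::case_match(.data$window,
      "pre8" ~ .data$hatch_doy - 1L,
      "pre_inc4" ~ .data$incubation_start_doy - 1L,
      "inc" ~ .data$hatch_doy - 1L,
      "post4" ~ .data$hatch_doy + 27L))
  if (any(w$start_doy < 1)) {
    abort("a window extends before day 1 of the year")
  }
  w[, c("year", "species", "window", "start_doy", "end_doy")]
}
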