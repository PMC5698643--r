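#' Phenology configuration
#'
#' Parameters controlling the derivation of phenological onset dates from a
#' daily weather series: the lapse-rate transfer from the meteorological
#' station to the study site, the growing-degree-day (GDD) model, the
#' frost-free moving-average width and the snow-free score threshold.
#'
#' @param lapse_rate temperature lapse rate, degrees C per 100 m of elevation
#'   (default 0.65).
#' @param elevation_diff elevation of the study site minus the station, in m
#'   (positive when the site is above the station); default 0.
#' @param gdd_base base temperature for degree-day accumulation, degrees C
#'   (default 5).
#' @param gdd_threshold cumulative degree-days defining the onset of summer
#'   (default 200, the point at which bilberry shoot growth is complete in
#'   the study system).
#' @param ma_window width in days of the centred moving average used for the
#'   frost-free date; must be odd (default 7).
#' @param snow_free_score largest snow-cover score (0--5 scale) still counted
#'   as snow-free (default 0, i.e. less than 20 percent cover).
#' @param gdd_start day-of-year on which degree-day accumulation begins
#'   (default 1, i.e. 1 January; winter days contribute nothing under the
#'   base-5 clamp so the choice is insensitive).
#' @return a named list of class `phenology_config`.
#' @examples
#' phenology_config(elevation_diff = 100)
#' @export
phenology_config <- function(lapse_rate = 0.65, elevation_diff = 0,
                             gdd_base = 5, gdd_threshold = 200,
                             ma_window = 7, snow_free_score = 0,
                             gdd_start = 1) {
  stopifnot(lapse_rate >= 0, is.finite(elevation_diff), gdd_threshold > 0,
            ma_window >= 1, ma_window %% 2 == 1,
            snow_free_score %in% 0:5, gdd_start >= 1)
  structure(
    list(lapse_rate = lapse_rate, elevation_diff = elevation_diff,
         gdd_base = gdd_base, gdd_threshold = gdd_threshold,
         ma_window = as.integer(ma_window),
         snow_free_score = as.integer(snow_free_score),
         gdd_start = as.integer(gdd_start)),
    class = "phenology_config")
}

#' Species breeding-date offsets
#'
#' Fixed intervals linking the observed capercaillie mating peak to derived
#' incubation-start and hatch dates, and the lags separating black grouse
#' from capercaillie. The interspecific lags (mating +5, incubation start
#' +8, hatching +6 days) come from long-term lek monitoring and
#' radio-collared females in the study system; the capercaillie
#' mating-to-hatch interval and incubation length are configurable because
#' only the lags are published.
#'
#' @param mating_lag_bg days black grouse mating peaks after capercaillie
#'   (default 5).
#' @param incubation_lag_bg days black grouse incubation starts after
#'   capercaillie (default 8).
#' @param hatch_lag_bg days black grouse hatches after capercaillie
#'   (default 6).
#' @param mating_to_hatch_cap days from capercaillie mating peak to hatching
#'   (default 38).
#' @param incubation_length_cap capercaillie incubation length in days
#'   (default 26; the remaining 12 days are the laying period).
#' @return a named list of class `breeding_offsets`.
#' @export
breeding_offsets <- function(mating_lag_bg = 5, incubation_lag_bg = 8,
                             hatch_lag_bg = 6, mating_to_hatch_cap = 38,
                             incubation_length_cap = 26) {
  if (min(mating_lag_bg, incubation_lag_bg, hatch_lag_bg) < 0) {
    abort("interspecific lags must be non-negative")
  }
  if (mating_to_hatch_cap <= 0 || incubation_length_cap <= 0) {
    abort("mating-to-hatch and incubation intervals must be positive")
  }
  if (incubation_length_cap >= mating_to_hatch_cap) {
    abort("incubation length must be shorter than the mating-to-hatch interval")
  }
  structure(
    list(mating_lag_bg = mating_lag_bg,
         incubation_lag_bg = incubation_lag_bg,
         hatch_lag_bg = hatch_lag_bg,
         mating_to_hatch_cap = mating_to_hatch_cap,
         incubation_length_cap = incubation_length_cap,
         laying_period_cap = mating_to_hatch_cap - incubation_length_cap),
    class = "breeding_offsets")
}
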