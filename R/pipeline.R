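# End-to-end analysis: from the four input tables to the full battery of
# trends, window responses, partial regressions and the mismatch fits.

#' Window temperatures joined to demographic indices
#'
#' Realizes the four breeding-season windows for each species-year,
#' computes their minimum-temperature means, and joins them (wide, one
#' column per window) to the demographic indices and transformed
#' covariates: the analysis table behind the window regressions.
#'
#' @param weather daily weather tibble.
#' @param phenology species-year phenology from
#'   [breeding_phenology_table()].
#' @param indices demographic indices from [demographic_indices()].
#' @param covariates tibble `year`, `rodent_index`, `fox_index`, or `NULL`
#'   to skip.
#' @return tibble with one row per species-year: the indices plus
#'   `t_pre8`, `t_pre_inc4`, `t_inc`, `t_post4` (window means of daily
#'   minimum temperature) and, when given, the transformed covariates.
#' @export
analysis_table <- function(weather, phenology, indices, covariates = NULL) {
  win <- build_windows(phenology)
  wm <- window_means(weather, win, vars = "t_min")
  wide <- tidyr::pivot_wider(
    wm[, c("year", "species", "window", "t_min_mean")],
    names_from = "window", values_from = "t_min_mean",
    names_prefix = "t_")
  out <- dplyr::left_join(indices, wide, by = c("year", "species"))
  if (!is.null(covariates)) {
    out <- dplyr::left_join(out, transform_covariates(covariates), by = "year")
  }
  out
}

#' Run the full climate-window regression battery
#'
#' For each species, each demographic index (breeding success, brood
#' frequency, brood size) and each of the four windows: the simple OLS
#' response of the index on the window's minimum-temperature mean, the
#' partial regression controlling for sqrt-rodents and log-fox (when
#' covariates are present), and the interspecific slope-difference test.
#'
#' @inheritParams analysis_table
#' @return tibble `response`, `window`, `species`, `n`, `beta`, `r`, `p`,
#'   `beta_partial`, `r_partial`, `p_partial`, `diff_beta_t`, `diff_beta_p`
#'   (difference columns repeated across the species pair).
#' @export
window_regressions <- function(weather, phenology, indices,
                               covariates = NULL) {
  tab <- analysis_table(weather, phenology, indices, covariates)
  metrics <- c("breeding_success", "brood_frequency", "brood_size")
  windows <- c("pre8", "pre_inc4", "inc", "post4")
  species <- unique(tab$species)
  grid <- tidyr::expand_grid(response = metrics, window = windows,
                             species = species)
  rows <- purrr::pmap(grid, function(response, window, species) {
    d <- tab[tab$species == species, ]
    d$.y <- d[[response]]
    d$.x <- d[[paste0("t_", window)]]
    fit <- temp_response(d, .y, .x)
    out <- tibble::tibble(response = response, window = window,
                          species = species, n = fit$n, beta = fit$beta,
                          se = fit$se, r = fit$r, p = fit$p)
    if (!is.null(covariates)) {
      pr <- partial_regression(d, .y, .x)
      out$beta_partial <- pr$beta_partial
      out$r_partial <- pr$r_partial
      out$p_partial <- pr$p
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  if (length(species) == 2) {
    diffs <- purrr::pmap(tidyr::expand_grid(response = metrics,
                                            window = windows),
                         function(response, window) {
      pair <- res[res$response == response & res$window == window, ]
      dt <- slope_difference_test(pair[1, ], pair[2, ])
      tibble::tibble(response = response, window = window,
                     diff_beta_t = dt$t, diff_beta_p = dt$p)
    })
    res <- dplyr::left_join(res, dplyr::bind_rows(diffs),
                            by = c("response", "window"))
  }
  res
}

#' Long-term trend battery for the demographic indices
#'
#' Per species and index: the OLS year trend (slope, r, p, total change)
#' and the AR(1)/AR(2) GLS AIC comparison justifying the OLS reporting.
#'
#' @param indices demographic indices from [demographic_indices()].
#' @param span_years study span for the total change (default from range).
#' @return tibble, one row per species x index.
#' @export
index_trends <- function(indices, span_years = NULL) {
  metrics <- c("breeding_success", "brood_frequency", "brood_size")
  grid <- tidyr::expand_grid(species = unique(indices$species),
                             variable = metrics)
  purrr::pmap_dfr(grid, function(species, variable) {
    d <- indices[indices$species == species, ]
    d$.y <- d[[variable]]
    tr <- ols_trend(d, .y, span_years = span_years)
    ar <- gls_ar_compare(d, .y)
    tibble::tibble(species = species, variable = variable, n = tr$n,
                   beta = tr$beta, se = tr$se, r = tr$r, p = tr$p,
                   delta = tr$delta, aic_ols = ar$aic_ols,
                   aic_ar1 = ar$aic_ar1, aic_ar2 = ar$aic_ar2,
                   ar_selected = ar$selected)
  })
}

#' Run the complete pipeline on a study bundle
#'
#' Convenience wrapper taking the four inputs (or a simulated
#' `grouse_study`) through every stage: onsets, phenology, indices, trend
#' battery, window regressions and the mismatch analysis per species.
#'
#' @param weather,survey,covariates,mating the four input tibbles, or pass
#'   a `grouse_study` as `weather` to use its components.
#' @param config a [phenology_config()].
#' @param offsets a [breeding_offsets()].
#' @return list with `onsets`, `phenology`, `indices`, `trends`,
#'   `responses`, `mismatch` (per-species [select_mismatch_model()]
#'   results).
#' @export
run_pipeline <- function(weather, survey = NULL, covariates = NULL,
                         mating = NULL, config = phenology_config(),
                         offsets = breeding_offsets()) {
  if (inherits(weather, "grouse_study")) {
    study <- weather
    weather <- study$weather
    survey <- study$survey
    covariates <- study$covariates
    mating <- study$mating
    offsets <- study$config$offsets
  }
  weather <- adjust_lapse_rate(weather, config)
  onsets <- phenology_onsets(weather, config)
  phenology <- breeding_phenology_table(mating[, c("year", "mating_doy")],
                                        offsets)
  indices <- demographic_indices(survey)
  trends <- index_trends(indices)
  responses <- window_regressions(weather, phenology, indices, covariates)
  pts <- compute_offsets(phenology, onsets, indices)
  mismatch <- lapply(split(pts, pts$species), select_mismatch_model)
  list(onsets = onsets, phenology = phenology, indices = indices,
       trends = trends, responses = responses, mismatch = mismatch)
}
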