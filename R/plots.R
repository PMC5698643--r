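# Diagnostic figures: annual index trends, phenology timelines.

#' Plot demographic index trends
#'
#' Annual breeding success, brood frequency and brood size per species with
#' OLS trend lines — the standard diagnostic panel for the long-term trend
#' battery.
#'
#' @param indices tibble from [demographic_indices()].
#' @return a ggplot object.
#' @export
plot_indices <- function(indices) {
  long <- tidyr::pivot_longer(
    indices,
    cols = c("breeding_success", "brood_frequency", "brood_size"),
    names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the phenology timeline
#'
#' Per-year onset dates (frost-free, snow-free, GDD threshold) together
#' with the species' mating and hatch dates: the at-a-glance picture of
#' how spring, summer and breeding shifted over the study.
#'
#' @param onsets tibble from [phenology_onsets()].
#' @param phenology tibble from [breeding_phenology_table()].
#' @return a ggplot object.
#' @export
plot_phenology <- function(onsets, phenology) {
  on_long <- tidyr::pivot_longer(onsets, -"year", names_to = "event",
                                 values_to = "doy")
  ph_long <- tidyr::pivot_longer(
    phenology, cols = c("mating_doy", "hatch_doy"),
    names_to = "event", values_to = "doy")
  ph_long$event <- paste(ph_long$species, sub("_doy", "", ph_long$event))
  both <- dplyr::bind_rows(on_long[, c("year", "event", "doy")],
                           ph_long[, c("year", "event", "doy")])
  ggplot2::ggplot(both, ggplot2::aes(.data$year, .data$doy,
                                     colour = .data$event)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = NULL, y = "day of year", colour = NULL) +
    ggplot2::theme_minimal()
}
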