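# Hatch-date mismatch analysis: signed offset between hatching and the
# GDD5 = 200 summer-onset date, and polynomial response curves of breeding
# success against that offset with AICc model selection.

#' Hatch-date offsets from the summer-onset date
#'
#' Joins per species-year hatch dates with the GDD-threshold onset dates and
#' breeding success, computing `offset_days = hatch_doy - gdd200_doy`
#' (negative = hatching before summer onset). Species-years missing any of
#' the three quantities are dropped with a message.
#'
#' @param phenology tibble with `year`, `species`, `hatch_doy`.
#' @param onsets tibble with `year`, `gdd200_doy` (see [gdd_onset_date()]).
#' @param indices tibble with `year`, `species`, `breeding_success`
#'   (see [demographic_indices()]).
#' @return tibble `year`, `species`, `offset_days`, `breeding_success`.
#' @export
compute_offsets <- function(phenology, onsets, indices) {
  check_columns(phenology, c("year", "species", "hatch_doy"), "phenology")
  check_columns(onsets, c("year", "gdd200_doy"), "onsets")
  check_columns(indices, c("year", "species", "breeding_success"), "indices")
  d <- dplyr::inner_join(phenology[, c("year", "species", "hatch_doy")],
                         onsets[, c("year", "gdd200_doy")], by = "year")
  d <- dplyr::inner_join(d, indices[, c("year", "species", "breeding_success")],
                         by = c("year", "species"))
  d <- dplyr::mutate(d, offset_days = .data$hatch_doy - .data$gdd200_doy)
  keep <- complete.cases(d$offset_days, d$breeding_success)
  if (any(!keep)) {
    inform(sprintf("dropping %d species-year(s) with missing dates or success",
                   sum(!keep)))
  }
  d[keep, c("year", "species", "offset_days", "breeding_success")]
}

#' Fit a polynomial mismatch response
#'
#' Least-squares polynomial (order 1 or 2) of breeding success on the
#' hatch-date offset. For an order-2 fit with a negative quadratic term the
#' stationary point `-b1 / (2 * b2)` is reported as the optimum offset.
#' The overall p-value is the F-test against the intercept-only model.
#'
#' @param points tibble from [compute_offsets()] (one species).
#' @param order polynomial order, 1 or 2.
#' @return an object of class `mismatch_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_mismatch <- function(points, order = 2) {
  stopifnot(order %in% 1:2)
  check_columns(points, c("offset_days", "breeding_success"), "points")
  pts <- points[complete.cases(points$offset_days, points$breeding_success), ]
  n <- nrow(pts)
  if (n < order + 2) abort(sprintf("need at least %d points for order %d", order + 2, order))
  if (stats::var(pts$offset_days) == 0) abort("degenerate design: all offsets equal")
  fml <- if (order == 1) breeding_success ~ offset_days
         else breeding_success ~ offset_days + I(offset_days^2)
  fit <- lm(fml, data = pts)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  cf <- coef(fit)
  optimum <- if (order == 2 && is.finite(cf[3]) && cf[3] < 0) {
    unname(-cf[2] / (2 * cf[3]))
  } else NA_real_
  structure(
    list(model = fit, order = order, n = n,
         species = if ("species" %in% names(pts)) unique(pts$species) else NA_character_,
         coefficients = cf, r_squared = sm$r.squared,
         p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
         aicc = aicc(fit), optimum_offset = optimum),
    class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("Mismatch fit (order %d, n = %d%s)\n", x$order, x$n,
              if (!is.na(x$species[1])) paste0(", ", paste(x$species, collapse = "/")) else ""))
  cf <- x$coefficients
  terms <- c("", " x", " x^2")[seq_along(cf)]
  cat("  y =", paste(sprintf("%+.4g%s", cf, terms), collapse = " "), "\n")
  cat(sprintf("  R^2 = %.3f, p = %.3g, AICc = %.2f\n",
              x$r_squared, x$p_value, x$aicc))
  if (!is.na(x$optimum_offset)) {
    cat(sprintf("  optimum offset = %.2f days\n", x$optimum_offset))
  }
  invisible(x)
}

#' @describeIn fit_mismatch coefficient table (term, estimate, std.error,
#'   statistic, p.value).
#' @param x,object a `mismatch_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mismatch_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = c("intercept", "linear", "quadratic")[seq_len(nrow(sm))],
                 estimate = sm[, 1], std.error = sm[, 2],
                 statistic = sm[, 3], p.value = sm[, 4])
}

#' @describeIn fit_mismatch one-row fit summary.
#' @exportS3Method generics::glance
glance.mismatch_fit <- function(x, ...) {
  tibble::tibble(order = x$order, n = x$n, r.squared = x$r_squared,
                 p.value = x$p_value, aicc = x$aicc,
                 optimum_offset = x$optimum_offset)
}

#' Select the mismatch response curve by small-sample AIC
#'
#' Fits the order-1 and order-2 polynomials and selects the one with the
#' lower AICc (small-sample corrected AIC, appropriate for ~40 annual
#' points and 2--3 parameters). Both fits are kept and reported.
#'
#' @inheritParams fit_mismatch
#' @return an object of class `mismatch_selection`: list with `fits` (both
#'   [fit_mismatch()] objects), `selected_order`, `best`, and a `table`
#'   combining both [glance()] rows with a `selected` flag.
#' @export
select_mismatch_model <- function(points) {
  pts <- points[complete.cases(points$offset_days, points$breeding_success), ]
  if (nrow(pts) < 4) abort("need at least 4 points for model selection")
  fits <- list(`1` = fit_mismatch(pts, 1), `2` = fit_mismatch(pts, 2))
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab$selected <- tab$aicc == min(tab$aicc)
  sel <- tab$order[tab$selected][1]
  structure(list(fits = fits, table = tab, selected_order = sel,
                 best = fits[[as.character(sel)]], points = pts),
            class = "mismatch_selection")
}

#' @export
print.mismatch_selection <- function(x, ...) {
  cat(sprintf("Mismatch model selection (AICc): order %d selected\n",
              x$selected_order))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn select_mismatch_model coefficients of the selected fit.
#' @param x,object a `mismatch_selection`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mismatch_selection <- function(x, ...) tidy(x$best)

#' @describeIn select_mismatch_model both fits' summary rows with the
#'   selection flag.
#' @exportS3Method generics::glance
glance.mismatch_selection <- function(x, ...) x$table

#' @describeIn select_mismatch_model scatter of breeding success against the
#'   hatch-date offset with both fitted curves (selected curve solid).
#' @exportS3Method ggplot2::autoplot
autoplot.mismatch_selection <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(offset_days = seq(min(pts$offset_days),
                                           max(pts$offset_days), length.out = 200))
  curves <- dplyr::bind_rows(lapply(object$fits, function(f) {
    dplyr::mutate(grid,
                  breeding_success = predict(f$model, newdata = grid),
                  order = factor(f$order),
                  selected = f$order == object$selected_order)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$offset_days, .data$breeding_success)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$order,
                                    linetype = !.data$selected)) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "hatch date relative to GDD5 = 200 (days)",
                  y = "breeding success (chicks per female)",
                  colour = "polynomial order") +
    ggplot2::theme_minimal()
}
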