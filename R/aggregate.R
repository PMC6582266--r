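#' Construct an aggregate time series
#'
#' One value per time index (calendar year or event time) for a named group
#' of countries, with the weighting scheme and the number of contributing
#' countries recorded. Usually produced by [weighted_aggregate()] or
#' [first_difference()] rather than directly.
#'
#' @param time Integer time index (strictly increasing).
#' @param value Numeric values (cigarettes per adult per year, or annual
#'   changes thereof when `differenced`).
#' @param n_countries Integer count of countries contributing per time point.
#' @param label Group label.
#' @param weighting `"population"` or `"unweighted"`.
#' @param differenced Whether values are year-over-year changes.
#' @return An `aggregate_series`: a data frame with columns `time`, `value`,
#'   `n_countries` and attributes `group_label`, `weighting`, `differenced`.
#' @export
aggregate_series <- function(time, value, n_countries = NA_integer_,
                             label = "all countries",
                             weighting = c("population", "unweighted"),
                             differenced = FALSE) {
  weighting <- match.arg(weighting)
  time <- as.integer(time)
  if (length(time) != length(value)) fail("time and value lengths differ")
  if (is.unsorted(time, strictly = TRUE)) fail("time index must be strictly increasing")
  out <- data.frame(time = time, value = as.numeric(value),
                    n_countries = as.integer(rep_len(n_countries, length(time))))
  structure(out, group_label = label, weighting = weighting,
            differenced = differenced,
            class = c("aggregate_series", "data.frame"))
}

#' @export
print.aggregate_series <- function(x, ...) {
  cat(sprintf("Aggregate series '%s' (%s%s): %d points, %d-%d\n",
              attr(x, "group_label"), attr(x, "weighting"),
              if (isTRUE(attr(x, "differenced"))) ", first-differenced" else "",
              nrow(x), min(x$time), max(x$time)))
  NextMethod()
}

#' @export
plot.aggregate_series <- function(x, ...,
                                  ylab = if (isTRUE(attr(x, "differenced")))
                                    "annual change (cigarettes/adult/year)"
                                  else "cigarettes/adult/year",
                                  xlab = "year", type = "l") {
  graphics::plot(x$time, x$value, type = type, xlab = xlab, ylab = ylab,
                 main = attr(x, "group_label"), ...)
  invisible(x)
}

#' Population-weighted aggregation of a country-year panel
#'
#' For each time point, the group value is the adult-population-weighted
#' mean of the per-adult outcome over the countries observed that year
#' (`weighting = "population"`), or the plain arithmetic mean
#' (`"unweighted"`). Countries missing in a year are excluded from both
#' numerator and denominator (per-year complete cases), so unbalanced
#' panels aggregate over whichever countries are present.
#'
#' With equal populations the two modes coincide, and the population mode
#' is invariant under rescaling all populations by a positive constant.
#'
#' @param panel A `country_panel`.
#' @param countries Optional character vector selecting the group's
#'   countries; `NULL` uses all.
#' @param weighting `"population"` (adult population, the outcome's own
#'   denominator) or `"unweighted"`.
#' @param label Group label carried into the result.
#' @return An [aggregate_series()].
#' @export
weighted_aggregate <- function(panel, countries = NULL,
                               weighting = c("population", "unweighted"),
                               label = NULL) {
  weighting <- match.arg(weighting)
  validate_panel(panel)
  if (is.null(label)) {
    label <- if (is.null(countries)) "all countries"
             else paste0("group of ", length(countries))
  }
  if (!is.null(countries)) {
    panel <- panel[panel$country %in% countries, , drop = FALSE]
  }
  if (!nrow(panel)) fail("empty group: %s", label)
  keep <- is.finite(panel$outcome)
  panel <- panel[keep, , drop = FALSE]
  if (!nrow(panel)) fail("empty group (no observed outcomes): %s", label)
  years <- sort(unique(panel$year))
  idx <- match(panel$year, years)
  if (weighting == "population") {
    num <- tapply(panel$outcome * panel$adult_population, idx, sum)
    den <- tapply(panel$adult_population, idx, sum)
    val <- as.numeric(num / den)
  } else {
    val <- as.numeric(tapply(panel$outcome, idx, mean))
  }
  n_c <- as.integer(tapply(panel$country, idx, function(z) length(unique(z))))
  aggregate_series(years, val, n_c, label = label, weighting = weighting)
}
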