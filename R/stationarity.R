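#' First-difference an aggregate series
#'
#' Converts levels into year-over-year changes, `dy_t = y_t - y_{t-1}`,
#' indexed at year `t`, so the downstream segmented regression describes
#' accelerations and decelerations of consumption rather than its level.
#' Gaps in the time index produce absent differences — a difference is
#' never taken across a gap.
#'
#' @param series An [aggregate_series()] of levels with at least 2 points.
#' @return An `aggregate_series` of differences (length = input length - 1
#'   when the index is contiguous), with attribute `differenced = TRUE`.
#' @examples
#' s <- aggregate_series(1970:1972, c(100, 150, 130))
#' first_difference(s)  # 50 at 1971, -20 at 1972
#' @export
first_difference <- function(series) {
  if (!inherits(series, "aggregate_series")) fail("series must be an aggregate_series")
  if (nrow(series) < 2L) fail("need at least 2 points to difference")
  adjacent <- diff(series$time) == 1L
  if (!any(adjacent)) fail("no adjacent years in the time index")
  keep <- which(adjacent) + 1L
  aggregate_series(series$time[keep],
                   series$value[keep] - series$value[keep - 1L],
                   pmin(series$n_countries[keep], series$n_countries[keep - 1L]),
                   label = attr(series, "group_label"),
                   weighting = attr(series, "weighting"),
                   differenced = TRUE)
}

# Finite-sample Dickey-Fuller critical values (Fuller's tabulation) for the
# t-ratio of the lagged level, by deterministic-term variant and sample
# size; interpolated linearly in 1/n between tabulated sizes.
.df_critical <- list(
  no_constant = cbind(
    n = c(25, 50, 100, 250, 500, Inf),
    `0.01` = c(-2.66, -2.62, -2.60, -2.58, -2.58, -2.58),
    `0.05` = c(-1.95, -1.95, -1.95, -1.95, -1.95, -1.95),
    `0.10` = c(-1.60, -1.61, -1.61, -1.62, -1.62, -1.62)),
  constant = cbind(
    n = c(25, 50, 100, 250, 500, Inf),
    `0.01` = c(-3.75, -3.58, -3.51, -3.46, -3.44, -3.43),
    `0.05` = c(-3.00, -2.93, -2.89, -2.88, -2.87, -2.86),
    `0.10` = c(-2.63, -2.60, -2.58, -2.57, -2.57, -2.57)),
  constant_trend = cbind(
    n = c(25, 50, 100, 250, 500, Inf),
    `0.01` = c(-4.38, -4.15, -4.04, -3.99, -3.98, -3.96),
    `0.05` = c(-3.60, -3.50, -3.45, -3.43, -3.42, -3.41),
    `0.10` = c(-3.24, -3.18, -3.15, -3.13, -3.13, -3.12))
)

df_critical_values <- function(variant, n) {
  tab <- .df_critical[[variant]]
  inv_n <- 1 / pmax(n, 25)          # below the smallest tabulated n, use n=25
  inv_tab <- 1 / tab[, "n"]
  vapply(c("0.01", "0.05", "0.10"), function(lv) {
    stats::approx(inv_tab, tab[, lv], xout = inv_n, rule = 2)$y
  }, numeric(1))
}

#' Dickey-Fuller unit-root test
#'
#' The simple (zero augmentation lags) Dickey-Fuller regression of
#' `dz_t` on `z_{t-1}`, optionally with a constant and a linear trend. The
#' statistic is the t-ratio of the `z_{t-1}` coefficient, compared against
#' finite-sample critical values for the chosen variant, and the result is
#' reported as a p-value bracket (`"<0.01"`, `"<0.05"`, `"<0.10"`,
#' `">=0.10"`) in the bracket style of published stationarity tables. Rejection
#' means the series is stationary. Applied to consumption levels the test
#' typically fails to reject; applied to the first-differenced series it
#' rejects, which is the precondition for the segmented regression.
#'
#' @param series An [aggregate_series()] (or numeric vector) with a
#'   contiguous time index and at least 8 points.
#' @param variant Deterministic terms: `"constant"` (default),
#'   `"no_constant"` or `"constant_trend"`. For the constant-including
#'   variants the statistic is invariant under adding a constant to the
#'   series.
#' @return A `df_test` with fields `statistic`, `p_bracket`, `n_obs`
#'   (observations in the test regression), `variant` and the critical
#'   values used.
#' @export
dickey_fuller <- function(series,
                          variant = c("constant", "no_constant",
                                      "constant_trend")) {
  variant <- match.arg(variant)
  z <- if (inherits(series, "aggregate_series")) {
    if (any(diff(series$time) != 1L)) fail("time index must be contiguous")
    series$value
  } else {
    as.numeric(series)
  }
  if (length(z) < 8L) fail("need at least 8 observations")
  if (stats::sd(z) == 0) fail("constant series: degenerate regression")
  dz <- diff(z)
  zlag <- z[-length(z)]
  tt <- seq_along(dz)
  fit <- switch(variant,
    no_constant = stats::lm(dz ~ zlag - 1),
    constant = stats::lm(dz ~ zlag),
    constant_trend = stats::lm(dz ~ zlag + tt))
  sm <- summary(fit)$coefficients
  if (!"zlag" %in% rownames(sm) || !is.finite(sm["zlag", 2]) ||
      sm["zlag", 2] == 0) {
    fail("degenerate Dickey-Fuller regression")
  }
  stat <- unname(sm["zlag", 1] / sm["zlag", 2])
  n_obs <- length(dz)
  cv <- df_critical_values(variant, n_obs)
  p_bracket <- if (stat < cv[["0.01"]]) "<0.01"
    else if (stat < cv[["0.05"]]) "<0.05"
    else if (stat < cv[["0.10"]]) "<0.10"
    else ">=0.10"
  structure(list(statistic = stat, p_bracket = p_bracket, n_obs = n_obs,
                 variant = variant, critical_values = cv,
                 series_label = if (inherits(series, "aggregate_series"))
                   attr(series, "group_label") else NULL),
            class = "df_test")
}

#' @export
print.df_test <- function(x, ...) {
  cat("Dickey-Fuller unit-root test (", x$variant, " variant, 0 lags)\n",
      sep = "")
  if (!is.null(x$series_label)) cat("  series:", x$series_label, "\n")
  cat(sprintf("  statistic = %.4f on %d obs, P %s\n", x$statistic, x$n_obs,
              x$p_bracket))
  cat(sprintf("  critical values: 1%% %.2f, 5%% %.2f, 10%% %.2f\n",
              x$critical_values[["0.01"]], x$critical_values[["0.05"]],
              x$critical_values[["0.10"]]))
  cat("  rejection => stationary\n")
  invisible(x)
}
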