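#' Interrupted time series (segmented regression) on a differenced series
#'
#' Fits, by ordinary least squares,
#'
#' `dy_t = b0 + b1 (t - t_first) + b2 D_t + b3 (t - cutoff) D_t + e_t`
#'
#' on a first-differenced aggregate series, where `D_t = 1` for
#' `t >= cutoff + 1` (a 2003 cutoff puts 2004 onwards in the post period,
#' with the cutoff-year observation in the pre period). Because the
#' outcome is the annual change in consumption, `b2` (level change) is a
#' one-time acceleration/deceleration of consumption at the cutoff and
#' `b3` (trend change) the ongoing change in that rate per year after it;
#' `b1` is the underlying linear trend of the annual change and `b0` the
#' constant. The trend-change clock is centred at the cutoff, so `b2` is
#' the discontinuity at the cutoff itself.
#'
#' Confidence intervals at 90/95/99% come from the t distribution with
#' `n - 4` degrees of freedom; each coefficient's significance tier is the
#' highest confidence level at which its interval excludes zero (the
#' dagger/double-dagger/section symbols of a published coefficient table).
#'
#' Before fitting, the series is checked for stationarity with
#' [dickey_fuller()]; a warning is raised when a unit root is not rejected
#' at the 5% level (the regression is still returned).
#'
#' @param diff_series A first-differenced [aggregate_series()] (see
#'   [first_difference()]). A contiguous time index with at least 3 points
#'   on each side of the cutoff is required.
#' @param spec An [intervention_spec()]; in ratification-centred mode the
#'   series must already be in event time (cutoff 0).
#' @param se_method `"classical"` OLS standard errors (default) or
#'   `"newey_west"` heteroskedasticity-and-autocorrelation-robust errors
#'   with one lag.
#' @param check_stationarity Run the Dickey-Fuller pre-check (skipped
#'   silently when the series is too short or degenerate).
#' @return An `its_fit` object: coefficients named `constant`,
#'   `underlying_trend`, `level_change`, `trend_change`, their standard
#'   errors, `ci` (a 4 x 2 x 3 array over 90/95/99%), `tier`, `n_obs`,
#'   `sigma`, `df`, the [dickey_fuller()] pre-check and the underlying
#'   `lm` fit.
#' @seealso [run_its_suite()] for whole-panel batches, [its_table()] for a
#'   publication-shaped coefficient table.
#' @export
fit_its <- function(diff_series, spec = intervention_spec(),
                    se_method = c("classical", "newey_west"),
                    check_stationarity = TRUE) {
  se_method <- match.arg(se_method)
  if (!inherits(diff_series, "aggregate_series")) {
    fail("diff_series must be an aggregate_series")
  }
  if (!inherits(spec, "intervention_spec")) fail("spec must be an intervention_spec")
  if (any(diff(diff_series$time) != 1L)) fail("time index must be contiguous")
  cutoff <- spec$cutoff_year
  time <- diff_series$time
  post <- as.numeric(time >= cutoff + 1L)
  if (sum(post == 0) < 3L || sum(post == 1) < 3L) {
    fail("need at least 3 observations on each side of the cutoff (pre %d, post %d)",
         sum(post == 0), sum(post == 1))
  }
  dat <- data.frame(dy = diff_series$value,
                    t_rel = time - time[1],
                    post = post,
                    t_post = (time - cutoff) * post)
  fit <- stats::lm(dy ~ t_rel + post + t_post, data = dat)
  if (anyNA(stats::coef(fit))) {
    fail("collinear design: cutoff too close to the series boundary")
  }

  df_check <- NULL
  if (isTRUE(check_stationarity)) {
    df_check <- tryCatch(dickey_fuller(diff_series), error = function(e) NULL)
    if (!is.null(df_check) && !df_check$p_bracket %in% c("<0.01", "<0.05")) {
      warning(sprintf(
        "Dickey-Fuller does not reject a unit root for '%s' (P %s); segmented regression may be spurious",
        attr(diff_series, "group_label"), df_check$p_bracket), call. = FALSE)
    }
  }

  # summary.lm warns on an exactly saturated (noiseless) fit; such fits are
  # legitimate here (closed-form recovery checks), so silence only that
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  vc <- switch(se_method,
    classical = sm$sigma^2 * sm$cov.unscaled,
    newey_west = sandwich::NeweyWest(fit, lag = 1, prewhite = FALSE,
                                     adjust = TRUE))
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  n <- nrow(dat)
  dfree <- n - 4L
  nm <- c("constant", "underlying_trend", "level_change", "trend_change")
  names(est) <- names(se) <- nm

  levels <- c(0.90, 0.95, 0.99)
  ci <- array(NA_real_, dim = c(4, 2, 3),
              dimnames = list(nm, c("lower", "upper"),
                              c("90%", "95%", "99%")))
  for (k in seq_along(levels)) {
    tq <- stats::qt(1 - (1 - levels[k]) / 2, dfree)
    ci[, 1, k] <- est - tq * se
    ci[, 2, k] <- est + tq * se
  }
  tier <- vapply(seq_along(est), function(i) {
    if (se[i] == 0) return(if (abs(est[i]) > 0) 99L else 0L)
    excl <- vapply(seq_along(levels), function(k) {
      ci[i, 1, k] > 0 || ci[i, 2, k] < 0
    }, logical(1))
    if (!any(excl)) 0L else as.integer(100 * max(levels[excl]))
  }, integer(1))
  names(tier) <- nm

  structure(list(coefficients = est, se = se, ci = ci, tier = tier,
                 vcov = vc, n_obs = n, df = dfree,
                 sigma = sm$sigma,
                 se_method = se_method, cutoff = spec,
                 stationarity = df_check,
                 group_label = attr(diff_series, "group_label"),
                 time = time, lm_fit = fit),
            class = "its_fit")
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
fitted.its_fit <- function(object, ...) stats::fitted(object$lm_fit)

#' @export
residuals.its_fit <- function(object, ...) stats::residuals(object$lm_fit)

#' @export
confint.its_fit <- function(object, parm, level = 0.95, ...) {
  lab <- sprintf("%d%%", round(100 * level))
  if (!lab %in% dimnames(object$ci)[[3]]) {
    tq <- stats::qt(1 - (1 - level) / 2, object$df)
    out <- cbind(object$coefficients - tq * object$se,
                 object$coefficients + tq * object$se)
  } else {
    out <- object$ci[, , lab]
  }
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predict annual changes from a segmented fit
#' @param object An `its_fit`.
#' @param time Integer years (or event times) at which to predict;
#'   defaults to the fitted index.
#' @param ... Unused.
#' @export
predict.its_fit <- function(object, time = object$time, ...) {
  cutoff <- object$cutoff$cutoff_year
  post <- as.numeric(time >= cutoff + 1L)
  X <- cbind(1, time - object$time[1], post, (time - cutoff) * post)
  drop(X %*% object$coefficients)
}

#' Simulate differenced series from a segmented fit
#' @inheritParams stats::simulate
#' @export
simulate.its_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sim_one <- function() {
    predict(object) + stats::rnorm(object$n_obs, 0, object$sigma)
  }
  runner <- function() {
    as.data.frame(replicate(nsim, sim_one()))
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Interrupted time series fit: '%s', cutoff %s, n = %d\n",
              x$group_label,
              if (x$cutoff$mode == "calendar") x$cutoff$cutoff_year
              else "T0 (ratification)",
              x$n_obs))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.its_fit <- function(object, ...) {
  marks <- c(`0` = "", `90` = "+", `95` = "*", `99` = "**")
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    lower95 = object$ci[, 1, "95%"],
    upper95 = object$ci[, 2, "95%"],
    tier = paste0(ifelse(object$tier > 0, object$tier, ""),
                  marks[as.character(object$tier)])
  )
  structure(list(table = tab, fit = object), class = "summary.its_fit")
}

#' @export
print.summary.its_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Interrupted time series (first-differenced outcome)\n"))
  cat(sprintf("  group: %s | cutoff: %s | n = %d | SEs: %s\n",
              f$group_label,
              if (f$cutoff$mode == "calendar") f$cutoff$cutoff_year
              else "T0 (ratification)",
              f$n_obs, f$se_method))
  if (!is.null(f$stationarity)) {
    cat(sprintf("  Dickey-Fuller on the differenced series: %.3f (P %s)\n",
                f$stationarity$statistic, f$stationarity$p_bracket))
  }
  stats::printCoefmat(cbind(Estimate = x$table$estimate, `Std. Error` = x$table$se,
                     `2.5%` = x$table$lower95, `97.5%` = x$table$upper95),
               digits = 4)
  cat("  tiers (highest CI excluding zero):",
      paste(rownames(x$table), x$table$tier, sep = ":", collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
plot.its_fit <- function(x, ...) {
  graphics::plot(x$time, x$lm_fit$model$dy, pch = 19, cex = 0.7,
                 xlab = "year", ylab = "annual change (cigarettes/adult/year)",
                 main = sprintf("ITS: %s", x$group_label), ...)
  cutoff <- x$cutoff$cutoff_year
  pre <- x$time <= cutoff
  graphics::lines(x$time[pre], predict(x, x$time[pre]), lwd = 2)
  graphics::lines(x$time[!pre], predict(x, x$time[!pre]), lwd = 2)
  graphics::abline(v = cutoff + 0.5, lty = 2)
  invisible(x)
}
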