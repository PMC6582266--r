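# In-sample-forecast event model: fit y_it = x_it' beta + e_it on
# pre-cutoff country-years, forecast the post-cutoff period from observed
# covariates, aggregate with population weights, and compare actual vs
# counterfactual consumption with prediction intervals.

#' Prepare a panel for event-model fitting
#'
#' Adds a numeric `year_index` (years since the panel's first year) and,
#' for distributed-lag variants, lagged covariate columns
#' `cov_*_lag1` / `cov_*_lag2` (matched within country on calendar year;
#' absent when the lagged year is missing). Lags are always of covariates,
#' never of the outcome — a lagged outcome would mechanically absorb any
#' break.
#'
#' @param panel A `country_panel`.
#' @param lags 0, 1 or 2 covariate lags.
#' @return A plain data frame ready for formula-based fitting.
#' @export
prepare_event_data <- function(panel, lags = 0L) {
  if (!lags %in% 0:2) fail("lags must be 0, 1 or 2")
  d <- as.data.frame(panel)
  d$year_index <- d$year - min(d$year)
  covs <- covariate_names(panel)
  if (lags > 0L && length(covs)) {
    key <- paste(d$country, d$year)
    for (l in seq_len(lags)) {
      idx <- match(paste(d$country, d$year - l), key)
      for (cv in covs) d[[paste0(cv, "_lag", l)]] <- d[[cv]][idx]
    }
  }
  d
}

#' Candidate specifications for the event model
#'
#' The configurable candidate family rendered from a panel's covariates:
#' covariate main effects, covariates with and interacted with the year
#' index, and covariates with and interacted with country indicators (the
#' "highly interacted" end of the family). All candidate terms are
#' available for every post-cutoff year, so each candidate can forecast.
#'
#' @param panel A `country_panel` with at least one covariate.
#' @param lags Covariate lags appended (additively) to every candidate.
#' @return A named list of right-hand-side formulas.
#' @export
event_candidates <- function(panel, lags = 0L) {
  covs <- covariate_names(panel)
  if (!length(covs)) fail("panel has no cov_* covariates")
  lag_terms <- if (lags > 0L) {
    unlist(lapply(seq_len(lags), function(l) paste0(covs, "_lag", l)))
  } else character(0)
  mk <- function(terms) stats::reformulate(c(terms, lag_terms))
  block <- paste0("(", paste(covs, collapse = " + "), ")")
  list(
    covariates = mk(covs),
    covariates_trend = mk(c(covs, "year_index")),
    covariates_x_trend = mk(paste(block, "* year_index")),
    covariates_country = mk(c(covs, "country")),
    covariates_x_country = mk(paste(block, "* country")),
    covariates_x_country_trend = mk(c(paste(block, "* country"), "year_index"))
  )
}

# countries with a complete (non-NA) record for `vars` on all their rows;
# lagged covariates are judged by their base column (head-of-series NAs in
# lag columns are structural, not missing data)
complete_case_countries <- function(data, vars) {
  vars <- unique(sub("_lag[12]$", "", vars))
  vars <- intersect(vars, names(data))
  if (!length(vars)) return(unique(data$country))
  ok <- stats::complete.cases(data[vars])
  bad <- unique(data$country[!ok])
  setdiff(unique(data$country), bad)
}

rhs_vars <- function(formula) setdiff(all.vars(formula), c("outcome"))

#' Select an event-model specification by k-fold cross-validation
#'
#' Candidates are scored on pre-cutoff observations only: folds partition
#' the pre-cutoff country-year rows reproducibly under `seed`, each
#' candidate is refitted k times and scored by the mean held-out squared
#' forecast error, and the candidate with the minimal score wins (ties go
#' to the candidate with fewest model terms). Countries with any missing
#' covariate are excluded first (with a log message, mirroring
#' missing-data exclusions in applied panels). A candidate whose design is
#' rank deficient in any training fold is skipped with a warning; if all
#' candidates are skipped, an error is raised.
#'
#' @param panel A `country_panel`.
#' @param candidates Named list of RHS formulas; default
#'   [event_candidates()].
#' @param cutoff Calendar cutoff year; only rows with `year <= cutoff` are
#'   used (the post period starts the year after).
#' @param k Fold count; `k` equal to the number of usable rows gives
#'   leave-one-out.
#' @param seed Integer seed for the fold assignment (mandatory).
#' @param lags Covariate lags added to every candidate.
#' @param quiet Suppress exclusion messages.
#' @return An `event_model_spec`: the selected formula with its label,
#'   `cv_score`, fold bookkeeping (`cv_k`, `cv_seed`), the per-candidate
#'   score table and the excluded countries.
#' @export
select_spec_kfold <- function(panel, candidates = NULL, cutoff = 2003,
                              k = 5, seed, lags = 0L, quiet = FALSE) {
  validate_panel(panel)
  if (missing(seed) || is.null(seed)) fail("seed is mandatory for fold assignment")
  if (is.null(candidates)) candidates <- event_candidates(panel, lags = lags)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    fail("candidates must be a named list of formulas")
  }
  data <- prepare_event_data(panel, lags = lags)
  needed <- unique(unlist(lapply(candidates, rhs_vars)))
  keep_countries <- complete_case_countries(data, needed)
  excluded <- setdiff(unique(data$country), keep_countries)
  if (length(excluded) && !quiet) {
    message(sprintf(
      "event model: excluded %d country(ies) with missing covariates: %s",
      length(excluded), paste(sort(excluded), collapse = ", ")))
  }
  if (!length(keep_countries)) fail("no complete-case countries remain")
  pre <- data[data$country %in% keep_countries & data$year <= cutoff, ,
              drop = FALSE]
  pre <- pre[stats::complete.cases(pre[intersect(needed, names(pre))]), ,
             drop = FALSE]
  n <- nrow(pre)
  if (!is_count(k) || k < 2 || k > n) fail("k must be between 2 and %d", n)
  pre$country <- factor(pre$country)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))

  score_one <- function(f) {
    full <- stats::update.formula(f, outcome ~ .)
    X_all <- stats::model.matrix(full, pre)
    p <- ncol(X_all)
    sq_err <- rep(NA_real_, n)
    for (fold in seq_len(k)) {
      train <- pre[folds != fold, , drop = FALSE]
      test <- pre[folds == fold, , drop = FALSE]
      fit <- stats::lm(full, data = train)
      if (fit$rank < p) return(list(score = NA_real_, p = p,
                                    skipped = "rank-deficient training design"))
      pred <- stats::predict(fit, newdata = test)
      sq_err[folds == fold] <- (test$outcome - pred)^2
    }
    list(score = mean(sq_err), p = p, skipped = NA_character_)
  }

  res <- lapply(candidates, score_one)
  scores <- data.frame(
    label = names(candidates),
    cv_score = vapply(res, `[[`, numeric(1), "score"),
    n_terms = vapply(res, `[[`, numeric(1), "p"),
    skipped = vapply(res, `[[`, character(1), "skipped"),
    stringsAsFactors = FALSE)
  for (i in which(!is.na(scores$skipped))) {
    warning(sprintf("candidate '%s' skipped: %s", scores$label[i],
                    scores$skipped[i]), call. = FALSE)
  }
  usable <- which(is.na(scores$skipped))
  if (!length(usable)) fail("all candidates skipped (rank-deficient designs)")
  best_sc <- min(scores$cv_score[usable])
  # scores equal up to numerical noise are ties, resolved by fewest terms
  tied <- usable[scores$cv_score[usable] <= best_sc + abs(best_sc) * 1e-6 + 1e-9]
  best <- tied[order(scores$n_terms[tied])][1]
  structure(list(formula = candidates[[best]], label = scores$label[best],
                 lags = as.integer(lags), cv_k = as.integer(k),
                 cv_seed = as.integer(seed),
                 cv_score = scores$cv_score[best],
                 n_terms = scores$n_terms[best],
                 scores = scores, cutoff = as.integer(cutoff),
                 excluded_countries = excluded),
            class = "event_model_spec")
}

#' @export
print.event_model_spec <- function(x, ...) {
  cat(sprintf(
    "Event-model specification '%s' (k = %d, seed = %d, cutoff %d)\n",
    x$label, x$cv_k, x$cv_seed, x$cutoff))
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  CV mean squared forecast error: %.6g (%d terms)\n",
              x$cv_score, x$n_terms))
  if (x$lags > 0) cat(sprintf("  distributed covariate lags: %d\n", x$lags))
  print(x$scores, row.names = FALSE, digits = 6)
  invisible(x)
}

as_event_spec <- function(spec, lags = 0L, cutoff = 2003) {
  if (inherits(spec, "event_model_spec")) return(spec)
  if (inherits(spec, "formula")) {
    return(structure(list(formula = spec, label = "fixed",
                          lags = as.integer(lags), cv_k = NA_integer_,
                          cv_seed = NA_integer_, cv_score = NA_real_,
                          n_terms = NA_integer_, scores = NULL,
                          cutoff = as.integer(cutoff),
                          excluded_countries = character(0)),
                     class = "event_model_spec"))
  }
  fail("spec must be an event_model_spec or a formula")
}

#' Add distributed covariate lags to a selected specification
#' @param spec An `event_model_spec`.
#' @param lags 1 or 2 covariate lags (of the covariates appearing in the
#'   spec), appended additively.
#' @return A new `event_model_spec` labelled `<label>+lagL`.
#' @export
add_spec_lags <- function(spec, lags) {
  spec <- as_event_spec(spec)
  if (!lags %in% 1:2) fail("lags must be 1 or 2")
  covs <- grep("^cov_[0-9]+$", all.vars(spec$formula), value = TRUE)
  if (!length(covs)) fail("spec has no cov_* terms to lag")
  lag_terms <- unlist(lapply(seq_len(lags), function(l) paste0(covs, "_lag", l)))
  out <- spec
  out$formula <- stats::update.formula(
    spec$formula, stats::reformulate(c(".", lag_terms)))
  out$lags <- as.integer(lags)
  out$label <- sprintf("%s+lag%d", spec$label, lags)
  out
}

#' Forecast the counterfactual and measure the gap to actual consumption
#'
#' Estimates `beta` by least squares on pre-cutoff rows only (no
#' post-cutoff information enters the fit), forecasts each country's
#' post-cutoff consumption from its observed covariates, aggregates actual
#' and counterfactual consumption with population weights, and reports the
#' per-year gap (actual minus counterfactual) with 80/90/95% prediction
#' intervals.
#'
#' The per-year prediction variance of the weighted aggregate, under
#' cross-country independence of the residuals, is
#' `sigma^2 (xbar' (X'X)^{-1} xbar + sum_i w_i^2)` with
#' `xbar = sum_i w_i x_{i,t}` — the linear-form variance of the common
#' coefficient estimate plus the weighted residual variance. Intervals use
#' the t distribution on the pre-period residual degrees of freedom.
#'
#' @param panel A `country_panel`.
#' @param spec An `event_model_spec` from [select_spec_kfold()] (or a bare
#'   RHS formula).
#' @param cutoff Calendar cutoff year; forecasts cover `cutoff + 1`
#'   onwards. Defaults to the spec's cutoff.
#' @param weighting `"population"` or `"unweighted"`.
#' @param quiet Suppress exclusion messages.
#' @return An `event_forecast`: `table` (year, actual, counterfactual,
#'   gap, `pi80`/`pi90`/`pi95` half-widths, countries per year), the
#'   coefficient vector, `sigma`, `df`, the in-sample pre-period aggregate
#'   fit, included countries and the weighting mode.
#' @export
forecast_counterfactual <- function(panel, spec, cutoff = NULL,
                                    weighting = c("population", "unweighted"),
                                    quiet = FALSE) {
  weighting <- match.arg(weighting)
  validate_panel(panel)
  spec <- as_event_spec(spec, cutoff = cutoff %||% 2003)
  cutoff <- cutoff %||% spec$cutoff
  data <- prepare_event_data(panel, lags = spec$lags)
  needed <- rhs_vars(spec$formula)
  keep_countries <- complete_case_countries(
    data[data$year <= cutoff, , drop = FALSE],
    setdiff(needed, c("country", "year_index")))
  excluded <- setdiff(unique(data$country), keep_countries)
  if (length(excluded) && !quiet) {
    message(sprintf(
      "event model: excluded %d country(ies) with missing pre-cutoff covariates: %s",
      length(excluded), paste(sort(excluded), collapse = ", ")))
  }
  data <- data[data$country %in% keep_countries, , drop = FALSE]
  data$country <- factor(data$country)
  pre <- data[data$year <= cutoff, , drop = FALSE]
  cc_vars <- intersect(needed, names(pre))
  pre <- pre[stats::complete.cases(pre[cc_vars]), , drop = FALSE]
  post <- data[data$year >= cutoff + 1L, , drop = FALSE]
  if (!nrow(post)) fail("no post-cutoff observations")
  bad <- !stats::complete.cases(post[intersect(cc_vars, names(post))])
  if (any(bad)) {
    i <- which(bad)[1]
    fail("post-cutoff covariate absent for country %s, year %d",
         post$country[i], post$year[i])
  }

  full <- stats::update.formula(spec$formula, outcome ~ .)
  fit <- stats::lm(full, data = pre)
  beta <- stats::coef(fit)
  keep <- !is.na(beta)
  r <- fit$rank
  n_pre <- nrow(pre)
  dfree <- n_pre - r
  if (dfree < 1) fail("pre-cutoff fit has no residual degrees of freedom")
  sigma2 <- sum(stats::residuals(fit)^2) / dfree
  # (X'X)^{-1} on the retained columns; a saturated noiseless fit is valid
  U <- withCallingHandlers(
    summary(fit)$cov.unscaled,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  tt <- stats::delete.response(stats::terms(fit))
  X0 <- stats::model.matrix(tt, post, xlev = fit$xlevels,
                            contrasts.arg = fit$contrasts)
  X0 <- X0[, names(beta)[keep], drop = FALSE]
  yhat <- drop(X0 %*% beta[keep])

  years <- sort(unique(post$year))
  tab <- data.frame(year = years, actual = NA_real_,
                    counterfactual = NA_real_, gap = NA_real_,
                    pi80 = NA_real_, pi90 = NA_real_, pi95 = NA_real_,
                    n_countries = NA_integer_)
  tq <- stats::qt(1 - (1 - c(0.80, 0.90, 0.95)) / 2, dfree)
  for (i in seq_along(years)) {
    rows <- which(post$year == years[i])
    w <- if (weighting == "population") {
      post$adult_population[rows] / sum(post$adult_population[rows])
    } else rep(1 / length(rows), length(rows))
    xbar <- drop(crossprod(X0[rows, , drop = FALSE], w))
    v <- sigma2 * (drop(crossprod(xbar, U %*% xbar)) + sum(w^2))
    tab$actual[i] <- sum(w * post$outcome[rows])
    tab$counterfactual[i] <- sum(w * yhat[rows])
    tab$gap[i] <- tab$actual[i] - tab$counterfactual[i]
    hw <- tq * sqrt(v)
    tab$pi80[i] <- hw[1]; tab$pi90[i] <- hw[2]; tab$pi95[i] <- hw[3]
    tab$n_countries[i] <- length(unique(post$country[rows]))
  }

  # in-sample pre-period aggregate (for plots and leakage checks)
  pre_fit <- stats::fitted(fit)
  pre_years <- sort(unique(pre$year))
  pre_tab <- data.frame(year = pre_years, actual = NA_real_,
                        fitted = NA_real_)
  for (i in seq_along(pre_years)) {
    rows <- which(pre$year == pre_years[i])
    w <- if (weighting == "population") {
      pre$adult_population[rows] / sum(pre$adult_population[rows])
    } else rep(1 / length(rows), length(rows))
    pre_tab$actual[i] <- sum(w * pre$outcome[rows])
    pre_tab$fitted[i] <- sum(w * pre_fit[rows])
  }

  structure(list(table = tab, pre_table = pre_tab, beta = beta,
                 sigma = sqrt(sigma2), df = dfree, n_pre = n_pre,
                 countries = levels(data$country),
                 excluded_countries = excluded,
                 weighting = weighting, cutoff = as.integer(cutoff),
                 spec = spec),
            class = "event_forecast")
}

#' @export
coef.event_forecast <- function(object, ...) object$beta

#' @export
fitted.event_forecast <- function(object, ...) {
  stats::setNames(object$pre_table$fitted, object$pre_table$year)
}

#' @export
residuals.event_forecast <- function(object, ...) {
  stats::setNames(object$pre_table$actual - object$pre_table$fitted,
                  object$pre_table$year)
}

#' @export
print.event_forecast <- function(x, ...) {
  cat(sprintf(
    "In-sample forecast event model: %d countries, cutoff %d, %s weights\n",
    length(x$countries), x$cutoff, x$weighting))
  cat(sprintf("  spec '%s', sigma = %.4g, df = %d\n", x$spec$label, x$sigma,
              x$df))
  print(x$table, digits = 5, row.names = FALSE)
  invisible(x)
}

#' @export
summary.event_forecast <- function(object, ...) {
  tab <- object$table
  last <- tab[nrow(tab), ]
  out <- list(
    cutoff = object$cutoff,
    n_countries = length(object$countries),
    final_year = last$year,
    final_gap = last$gap,
    final_pi = c(pi80 = last$pi80, pi90 = last$pi90, pi95 = last$pi95),
    years_outside_95 = tab$year[abs(tab$gap) > tab$pi95],
    table = tab)
  class(out) <- "summary.event_forecast"
  out
}

#' @export
print.summary.event_forecast <- function(x, ...) {
  cat(sprintf("Event-model counterfactual, cutoff %d (%d countries)\n",
              x$cutoff, x$n_countries))
  cat(sprintf(
    "  gap in %d: %.1f cigarettes/adult/year (95%% PI half-width %.1f)\n",
    x$final_year, x$final_gap, x$final_pi["pi95"]))
  if (length(x$years_outside_95)) {
    cat("  years outside the 95% prediction interval:",
        paste(x$years_outside_95, collapse = ", "), "\n")
  } else {
    cat("  no year falls outside the 95% prediction interval\n")
  }
  invisible(x)
}

#' @export
plot.event_forecast <- function(x, ...) {
  tab <- x$table
  pre <- x$pre_table
  xl <- range(pre$year, tab$year)
  yl <- range(pre$actual, tab$actual, tab$counterfactual - tab$pi95,
              tab$counterfactual + tab$pi95)
  graphics::plot(NA, xlim = xl, ylim = yl, xlab = "year",
                 ylab = "cigarettes/adult/year",
                 main = "Actual vs counterfactual consumption", ...)
  shade <- function(hw, col) {
    graphics::polygon(c(tab$year, rev(tab$year)),
                      c(tab$counterfactual - hw, rev(tab$counterfactual + hw)),
                      border = NA, col = col)
  }
  shade(tab$pi95, grDevices::adjustcolor("grey70", 0.5))
  shade(tab$pi90, grDevices::adjustcolor("grey55", 0.5))
  shade(tab$pi80, grDevices::adjustcolor("grey40", 0.5))
  graphics::lines(pre$year, pre$actual, lwd = 2)
  graphics::lines(tab$year, tab$actual, lwd = 2)
  graphics::lines(c(pre$year, tab$year),
                  c(pre$fitted, tab$counterfactual), lty = 2, lwd = 2)
  graphics::abline(v = x$cutoff + 0.5, lty = 3)
  invisible(x)
}

#' Run the event model over groups and robustness variants
#'
#' For every country group the specification is selected once by k-fold
#' cross-validation on the group's pre-cutoff data (unless a fixed `spec`
#' is supplied), then forecast under each requested variant: `"base"`,
#' distributed covariate lags (`"lag1"`, `"lag2"`), and `"unweighted"`
#' aggregation. Named exclusion sets add further variants (e.g. dropping
#' the largest consumer). Variant failures are recorded, not fatal.
#'
#' @param panel A `country_panel`.
#' @param cutoff Calendar cutoff year.
#' @param seed Seed for fold assignment (mandatory unless `spec` given).
#' @param k Fold count.
#' @param candidates Candidate formulas (default [event_candidates()]).
#' @param spec Optional fixed specification, skipping selection.
#' @param groupings,extra_groups See [panel_groups()].
#' @param variants Subset of `c("base", "lag1", "lag2", "unweighted")`.
#' @param exclude Named list of country sets; each adds an
#'   `excluding <name>` variant.
#' @param quiet Suppress log messages.
#' @return An `event_suite`: records with `scheme`, `group`, `variant` and
#'   either `forecast` or `skipped`. Flatten with [forecast_table()].
#' @export
run_event_suite <- function(panel, cutoff = 2003, seed = NULL, k = 5,
                            candidates = NULL, spec = NULL,
                            groupings = c("all", "income", "region"),
                            extra_groups = NULL,
                            variants = c("base", "lag1", "lag2", "unweighted"),
                            exclude = NULL, quiet = TRUE) {
  validate_panel(panel)
  variants <- match.arg(variants, several.ok = TRUE)
  groups <- panel_groups(panel, groupings, extra_groups)
  records <- list()
  add <- function(scheme, group, variant, res) {
    rec <- list(scheme = scheme, group = group, variant = variant)
    if (inherits(res, "error")) {
      rec$skipped <- conditionMessage(res)
      if (!quiet) message(sprintf("event suite: skipped %s / %s: %s",
                                  group, variant, rec$skipped))
    } else rec$forecast <- res
    records[[length(records) + 1L]] <<- rec
  }
  for (g in groups) {
    gp <- panel[panel$country %in% g$countries, , drop = FALSE]
    class(gp) <- c("country_panel", "data.frame")
    gspec <- tryCatch({
      if (!is.null(spec)) as_event_spec(spec, cutoff = cutoff)
      else select_spec_kfold(gp, candidates = candidates, cutoff = cutoff,
                             k = k, seed = seed, quiet = quiet)
    }, error = function(e) e)
    if (inherits(gspec, "error")) {
      for (v in variants) add(g$scheme, g$label, v, gspec)
      next
    }
    for (v in variants) {
      res <- tryCatch(switch(v,
        base = forecast_counterfactual(gp, gspec, cutoff, quiet = quiet),
        lag1 = forecast_counterfactual(gp, add_spec_lags(gspec, 1), cutoff,
                                       quiet = quiet),
        lag2 = forecast_counterfactual(gp, add_spec_lags(gspec, 2), cutoff,
                                       quiet = quiet),
        unweighted = forecast_counterfactual(gp, gspec, cutoff,
                                             weighting = "unweighted",
                                             quiet = quiet)),
        error = function(e) e)
      add(g$scheme, g$label, v, res)
    }
    if (g$scheme == "all" && !is.null(exclude)) {
      for (nm in names(exclude)) {
        res <- tryCatch({
          sub <- exclude_countries(gp, exclude[[nm]], quiet = quiet)
          forecast_counterfactual(sub, gspec, cutoff, quiet = quiet)
        }, error = function(e) e)
        add(g$scheme, g$label, paste0("excluding ", nm), res)
      }
    }
  }
  structure(records, class = "event_suite")
}

#' Flatten an event suite into a long forecast table
#'
#' One row per post-cutoff year per group/variant: actual, counterfactual,
#' gap and the 80/90/95% prediction-interval half-widths.
#'
#' @param suite An `event_suite` from [run_event_suite()].
#' @return A data frame (skipped variants contribute a single row with the
#'   reason).
#' @export
forecast_table <- function(suite) {
  stopifnot(inherits(suite, "event_suite"))
  rows <- lapply(suite, function(rec) {
    if (!is.null(rec$skipped)) {
      return(data.frame(scheme = rec$scheme, group = rec$group,
                        variant = rec$variant, year = NA_integer_,
                        actual = NA_real_, counterfactual = NA_real_,
                        gap = NA_real_, pi80 = NA_real_, pi90 = NA_real_,
                        pi95 = NA_real_, n_countries = NA_integer_,
                        skipped = rec$skipped, stringsAsFactors = FALSE))
    }
    tab <- rec$forecast$table
    cbind(data.frame(scheme = rec$scheme, group = rec$group,
                     variant = rec$variant, stringsAsFactors = FALSE),
          tab, skipped = NA_character_)
  })
  do.call(rbind, rows)
}

#' @export
print.event_suite <- function(x, ...) {
  done <- sum(vapply(x, function(r) is.null(r$skipped), logical(1)))
  cat(sprintf("Event-model suite: %d group/variant runs (%d fitted, %d skipped)\n",
              length(x), done, length(x) - done))
  tab <- forecast_table(x)
  last <- tab[!is.na(tab$year) & ave(tab$year, tab$group, tab$variant,
                                     FUN = max) == tab$year, ]
  print(last[c("group", "variant", "year", "gap", "pi95")], digits = 4,
        row.names = FALSE)
  invisible(x)
}
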