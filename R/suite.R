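# Grouping schemes shared by the ITS and event-model suites.

#' Enumerate country groups of a panel
#'
#' Expands grouping-scheme names into named country sets: `"all"` (every
#' country), `"income"` (one group per income tier), `"region"` (one per
#' UN region), `"oecd"` (members vs non-members). `extra_groups` adds
#' custom sets (e.g. excluding the largest consumer, the non-divided
#' countries, or single top-consuming countries).
#'
#' @param panel A `country_panel`.
#' @param groupings Character vector of scheme names.
#' @param extra_groups Named list of character vectors of country ids.
#' @return A list of `list(scheme, label, countries)` entries.
#' @export
panel_groups <- function(panel, groupings = c("all", "income", "region", "oecd"),
                         extra_groups = NULL) {
  known <- c("all", "income", "region", "oecd")
  bad <- setdiff(groupings, known)
  if (length(bad)) {
    fail("unknown grouping scheme(s): %s (known: %s)",
         paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  info <- unique(as.data.frame(panel)[c("country", "region", "income", "oecd")])
  out <- list()
  add <- function(scheme, label, countries) {
    out[[length(out) + 1L]] <<- list(scheme = scheme, label = label,
                                     countries = countries)
  }
  for (g in groupings) {
    switch(g,
      all = add("all", "all countries", info$country),
      income = for (lv in sort(unique(info$income))) {
        add("income", lv, info$country[info$income == lv])
      },
      region = for (lv in sort(unique(info$region))) {
        add("region", lv, info$country[info$region == lv])
      },
      oecd = {
        add("oecd", "OECD", info$country[info$oecd])
        add("oecd", "non-OECD", info$country[!info$oecd])
      })
  }
  if (!is.null(extra_groups)) {
    if (is.null(names(extra_groups)) || any(!nzchar(names(extra_groups)))) {
      fail("extra_groups must be a named list")
    }
    for (nm in names(extra_groups)) add("extra", nm, extra_groups[[nm]])
  }
  out
}

#' Run the interrupted time series analysis over groups and variants
#'
#' For every intervention variant (e.g. the primary 2003 calendar cutoff,
#' the secondary 1999 cutoff, and the ratification-centred realignment)
#' and every country group, aggregates the panel, first-differences the
#' aggregate and fits [fit_its()]. Groups whose series are too short (or
#' otherwise unfittable) are skipped with a logged reason rather than
#' failing the whole suite.
#'
#' @param panel A `country_panel`.
#' @param groupings,extra_groups See [panel_groups()].
#' @param specs Named list of [intervention_spec()] variants.
#' @param weighting Passed to [weighted_aggregate()].
#' @param se_method Passed to [fit_its()].
#' @param check_stationarity Passed to [fit_its()].
#' @return An `its_suite`: a list of records with `scheme`, `group`,
#'   `variant`, `n_obs`, and either `fit` (an `its_fit`) or `skipped`
#'   (the reason). [its_table()] flattens it to a coefficient table.
#' @export
run_its_suite <- function(panel,
                          groupings = c("all", "income", "region", "oecd"),
                          extra_groups = NULL,
                          specs = list(primary = intervention_spec()),
                          weighting = "population",
                          se_method = "classical",
                          check_stationarity = TRUE) {
  validate_panel(panel)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    fail("specs must be a named list of intervention_spec objects")
  }
  groups <- panel_groups(panel, groupings, extra_groups)
  records <- list()
  for (v in names(specs)) {
    spec <- specs[[v]]
    working <- if (spec$mode == "ratification_centered") {
      realign_to_event_time(panel, spec, quiet = TRUE)
    } else panel
    for (g in groups) {
      rec <- list(scheme = g$scheme, group = g$label, variant = v)
      res <- tryCatch({
        agg <- weighted_aggregate(working, g$countries,
                                  weighting = weighting, label = g$label)
        d <- first_difference(agg)
        fit_its(d, spec, se_method = se_method,
                check_stationarity = check_stationarity)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rec$skipped <- conditionMessage(res)
        rec$n_obs <- NA_integer_
        message(sprintf("ITS suite: skipped %s / %s (%s): %s",
                        v, g$label, g$scheme, rec$skipped))
      } else {
        rec$fit <- res
        rec$n_obs <- res$n_obs
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(records, class = "its_suite")
}

#' Flatten an ITS suite into a publication-shaped coefficient table
#'
#' One row per group x variant with, for each of the four coefficients
#' (underlying trend, level change at the cutoff, trend change after it,
#' constant): estimate, standard error, 95% CI bounds and significance
#' tier (0/90/95/99), plus the observation count.
#'
#' @param suite An `its_suite` from [run_its_suite()].
#' @return A data frame; skipped groups appear with `NA` estimates and the
#'   skip reason.
#' @export
its_table <- function(suite) {
  stopifnot(inherits(suite, "its_suite"))
  term_order <- c("underlying_trend", "level_change", "trend_change",
                  "constant")
  rows <- lapply(suite, function(rec) {
    base <- data.frame(variant = rec$variant, scheme = rec$scheme,
                       group = rec$group, n_obs = rec$n_obs,
                       stringsAsFactors = FALSE)
    if (!is.null(rec$skipped)) {
      base$skipped <- rec$skipped
      return(base)
    }
    f <- rec$fit
    for (term in term_order) {
      base[[paste0(term, "_est")]] <- unname(f$coefficients[term])
      base[[paste0(term, "_se")]] <- unname(f$se[term])
      base[[paste0(term, "_lo95")]] <- f$ci[term, "lower", "95%"]
      base[[paste0(term, "_hi95")]] <- f$ci[term, "upper", "95%"]
      base[[paste0(term, "_tier")]] <- unname(f$tier[term])
    }
    base$skipped <- NA_character_
    base
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  do.call(rbind, rows)
}

#' @export
print.its_suite <- function(x, ...) {
  fitted <- sum(vapply(x, function(r) is.null(r$skipped), logical(1)))
  cat(sprintf("ITS suite: %d group/variant runs (%d fitted, %d skipped)\n",
              length(x), fitted, length(x) - fitted))
  tab <- its_table(x)
  cols <- intersect(c("variant", "group", "level_change_est",
                      "level_change_se", "level_change_tier",
                      "trend_change_est", "trend_change_tier", "n_obs"),
                    names(tab))
  print(tab[cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Stationarity report for a panel's aggregate series
#'
#' For each group, runs [dickey_fuller()] on the aggregate level series
#' and on its first difference — the pre-analysis check that levels are
#' non-stationary while annual changes are stationary.
#'
#' @inheritParams run_its_suite
#' @param variant Dickey-Fuller deterministic-term variant.
#' @return A data frame with one row per group and series form.
#' @export
stationarity_table <- function(panel,
                               groupings = c("all", "income", "region", "oecd"),
                               extra_groups = NULL,
                               weighting = "population",
                               variant = "constant") {
  validate_panel(panel)
  groups <- panel_groups(panel, groupings, extra_groups)
  rows <- list()
  for (g in groups) {
    agg <- tryCatch(weighted_aggregate(panel, g$countries,
                                       weighting = weighting,
                                       label = g$label),
                    error = function(e) NULL)
    if (is.null(agg)) next
    for (form in c("levels", "differences")) {
      s <- if (form == "levels") agg else
        tryCatch(first_difference(agg), error = function(e) NULL)
      if (is.null(s)) next
      dfres <- tryCatch(dickey_fuller(s, variant = variant),
                        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = g$scheme, group = g$label, series = form,
        statistic = if (is.null(dfres)) NA_real_ else dfres$statistic,
        p_bracket = if (is.null(dfres)) NA_character_ else dfres$p_bracket,
        n_obs = if (is.null(dfres)) NA_integer_ else dfres$n_obs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
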