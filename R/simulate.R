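#' Default stratum specification for synthetic panels
#'
#' Four strata emulating the heterogeneity of observed cigarette
#' consumption: a declining high-income/OECD stratum, a rising
#' upper-middle-income Asian stratum, a slowly rising lower-middle-income
#' stratum and a slowly declining low-income stratum. Baselines are levels
#' at the first year (cigarettes/adult/year), trends are pre-intervention
#' slopes (cigarettes/adult/year per year), and `level_change` /
#' `slope_change` are injected breaks on the first-differenced scale
#' (zero by default: a null intervention).
#'
#' @return A data frame with one row per stratum and columns `name`,
#'   `baseline`, `trend`, `level_change`, `slope_change`, `pop_min`,
#'   `pop_max`, `region`, `income`, `oecd`.
#' @export
default_strata <- function() {
  data.frame(
    name = c("high_income", "upper_middle", "lower_middle", "low_income"),
    baseline = c(2800, 1400, 1000, 800),
    trend = c(-30, 20, 5, -5),
    level_change = 0,
    slope_change = 0,
    pop_min = c(2e6, 5e6, 3e6, 1e6),
    pop_max = c(8e7, 2e8, 1.5e8, 5e7),
    region = c("Europe", "Asia", "Americas", "Africa"),
    income = c("High income", "Upper middle income", "Lower middle income",
               "Low income"),
    oecd = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic country-year panel generator
#'
#' Bundles and validates every knob of [generate_panel()]. Defaults mirror
#' the structure of the motivating application: 71 countries observed
#' annually over 1970-2015, near-linear per-stratum trends of opposite
#' signs, a 2003 intervention with injected breaks expressed on the
#' first-differenced scale, slow-moving AR(1) covariates, random-walk
#' residual innovations (levels are unit-root non-stationary, their annual
#' changes stationary), occasional missing country-years, and
#' ratification years staggered 1-5 years after the intervention.
#'
#' @param n_countries Number of countries.
#' @param year_range Inclusive calendar interval `c(first, last)`; must
#'   span at least 10 years.
#' @param strata Stratum specification as in [default_strata()]; countries
#'   are assigned round-robin so every country belongs to exactly one
#'   stratum (hence one region / income tier / OECD flag).
#' @param intervention_year Calendar year of the intervention; injected
#'   breaks act on annual changes from `intervention_year + 1` onwards.
#' @param n_covariates Number of `cov_*` covariates.
#' @param covariate_effects Effect of each covariate on the outcome level
#'   (cigarettes/adult/year per covariate unit); recycled to
#'   `n_covariates`.
#' @param noise_sd Residual innovation standard deviation
#'   (cigarettes/adult/year).
#' @param noise `"random_walk"` (default): innovations accumulate in the
#'   level so the first-differenced residuals are iid — the regime the
#'   interrupted time series analysis assumes. `"iid"`: independent level
#'   noise — the regime under which the event regression model is exactly
#'   correct.
#' @param missing_rate Fraction of country-years dropped uniformly at
#'   random (a country's first year is never dropped, so differencing
#'   keeps its anchor). In `[0, 1)`.
#' @param ratification_offsets Integer year offsets of each country's
#'   ratification year from `intervention_year`; recycled to
#'   `n_countries`. Default `1:5` staggered.
#' @param seed Integer seed; fixing it fixes the emitted panel
#'   byte-for-byte.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_countries = 71L,
                       year_range = c(1970L, 2015L),
                       strata = default_strata(),
                       intervention_year = 2003L,
                       n_covariates = 3L,
                       covariate_effects = c(60, 40, 25),
                       noise_sd = 30,
                       noise = c("random_walk", "iid"),
                       missing_rate = 0.02,
                       ratification_offsets = NULL,
                       seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(n_countries = n_countries, year_range = year_range,
              strata = strata, intervention_year = intervention_year,
              n_covariates = n_covariates,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd, noise = noise,
              missing_rate = missing_rate,
              ratification_offsets = ratification_offsets, seed = seed)

  if (!is_count(cfg$n_countries)) fail("invalid config field 'n_countries': must be a positive count")
  if (length(cfg$year_range) != 2L || !is_year(cfg$year_range[1]) ||
      !is_year(cfg$year_range[2]) ||
      cfg$year_range[2] - cfg$year_range[1] < 9) {
    fail("invalid config field 'year_range': must span at least 10 years")
  }
  if (!is.data.frame(cfg$strata) || !nrow(cfg$strata) ||
      !all(c("name", "baseline", "trend", "level_change", "slope_change",
             "pop_min", "pop_max", "region", "income", "oecd") %in%
             names(cfg$strata))) {
    fail("invalid config field 'strata': see default_strata() for the schema")
  }
  if (any(cfg$strata$pop_min <= 0 | cfg$strata$pop_max < cfg$strata$pop_min)) {
    fail("invalid config field 'strata': population ranges must be positive")
  }
  if (!is_year(cfg$intervention_year)) fail("invalid config field 'intervention_year'")
  if (!is.numeric(cfg$n_covariates) || cfg$n_covariates < 0 ||
      cfg$n_covariates != round(cfg$n_covariates)) {
    fail("invalid config field 'n_covariates': must be a non-negative count")
  }
  cfg$n_covariates <- as.integer(cfg$n_covariates)
  if (cfg$n_covariates > 0) {
    cfg$covariate_effects <- rep_len(as.numeric(cfg$covariate_effects),
                                     cfg$n_covariates)
  } else {
    cfg$covariate_effects <- numeric(0)
  }
  if (!is.numeric(cfg$noise_sd) || length(cfg$noise_sd) != 1L ||
      cfg$noise_sd < 0) {
    fail("invalid config field 'noise_sd': must be >= 0")
  }
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 ||
      cfg$missing_rate >= 1) {
    fail("invalid config field 'missing_rate': must be in [0, 1)")
  }
  if (is.null(cfg$ratification_offsets)) cfg$ratification_offsets <- 1:5
  if (any(cfg$ratification_offsets != round(cfg$ratification_offsets))) {
    fail("invalid config field 'ratification_offsets': must be integers")
  }
  cfg$ratification_offsets <- rep_len(as.integer(cfg$ratification_offsets),
                                      cfg$n_countries)
  if (!is_count(abs(cfg$seed) + 1)) fail("invalid config field 'seed'")
  cfg$year_range <- as.integer(cfg$year_range)
  cfg$intervention_year <- as.integer(cfg$intervention_year)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# covariate AR(1) parameters: slow-moving national indicators
.cov_ar <- 0.80     # within-country autocorrelation
.cov_sd <- 0.30     # marginal sd around the covariate mean of 1
.cov_offset_sd <- 0.30  # country fixed offsets

#' Generate a synthetic country-year panel with known injected effects
#'
#' Builds a panel whose outcome for country i of stratum s in year t is
#'
#' `baseline_s + trend_s (t - t0) + B_s(t) + sum_j gamma_j x_ijt + e_it`
#'
#' where `B_s(t)` accumulates the injected first-differenced breaks
#' (`level_change_s` once per year plus `slope_change_s (t - cutoff)` for
#' every post-cutoff year, so the ANNUAL CHANGE jumps by `level_change_s`
#' from `cutoff + 1` onwards and its slope changes by `slope_change_s`),
#' covariates are AR(1) within country around country-specific means, and
#' `e_it` follows the configured noise process. Outcomes are truncated at
#' zero (consumption cannot be negative; with the default baselines this
#' is vanishingly rare). A fraction `missing_rate` of country-years is then
#' dropped at random, never a country's first year.
#'
#' @param config A [sim_config()].
#' @return A list with elements `panel` (a validated `country_panel`) and
#'   `truth` (a `sim_truth` recording every injected parameter).
#' @examples
#' sim <- generate_panel(sim_config(n_countries = 8, seed = 42))
#' head(sim$panel)
#' sim$truth$strata
#' @export
generate_panel <- function(config) {
  generate_core(config, post_shift = NULL)
}

#' Generate a panel whose covariate-outcome link shifts after the cutoff
#'
#' Identical to [generate_panel()] under the same seed, except that from
#' `intervention_year + 1` onwards the covariate effects change by
#' `post_shift`, adding `sum_j shift_sj x_ijt` to the outcome. Because the
#' covariates have mean 1, a total shift of `+s` raises post-cutoff
#' consumption by about `s` per adult per year relative to the
#' pre-cutoff covariate model — a known forecast gap for testing the event
#' model, which assumes this link is stable.
#'
#' @inheritParams generate_panel
#' @param post_shift Effect-size change per covariate: a numeric vector
#'   recycled to `n_covariates` (all strata), or a matrix with one row per
#'   stratum and one column per covariate for stratum-specific shifts
#'   (e.g. offsetting shifts of opposite sign).
#' @return As [generate_panel()]; `truth$post_shift` records the shifts.
#' @export
generate_covariate_shift_panel <- function(config, post_shift) {
  if (is.null(post_shift)) fail("post_shift must be supplied")
  generate_core(config, post_shift = post_shift)
}

generate_core <- function(config, post_shift = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_countries
  years <- config$year_range[1]:config$year_range[2]
  ny <- length(years)
  S <- nrow(config$strata)
  J <- config$n_covariates
  cutoff <- config$intervention_year

  stratum_of <- rep_len(seq_len(S), n)
  country <- sprintf(paste0("C%0", max(2L, nchar(n)), "d"), seq_len(n))

  shift_mat <- NULL
  if (!is.null(post_shift)) {
    if (is.matrix(post_shift)) {
      if (nrow(post_shift) != S || ncol(post_shift) != J) {
        fail("post_shift matrix must be n_strata x n_covariates (%d x %d)", S, J)
      }
      shift_mat <- post_shift
    } else {
      shift_mat <- matrix(rep_len(as.numeric(post_shift), J), nrow = S,
                          ncol = J, byrow = TRUE)
    }
  }

  # per-year injected break on the differenced scale, cumulated into levels
  post <- years >= cutoff + 1L
  diff_break <- function(level, slope) {
    ifelse(post, level + slope * (years - cutoff), 0)
  }
  cum_break <- vapply(seq_len(S), function(s) {
    cumsum(diff_break(config$strata$level_change[s],
                      config$strata$slope_change[s]))
  }, numeric(ny))

  out <- with_seed(config$seed, {
    pop <- stats::runif(n, config$strata$pop_min[stratum_of],
                        config$strata$pop_max[stratum_of])
    # covariates: x_ijt = 1 + a_ij + u_ijt, u AR(1)
    x <- array(0, dim = c(n, ny, max(J, 1L)))
    if (J > 0) {
      innov_sd <- .cov_sd * sqrt(1 - .cov_ar^2)
      for (j in seq_len(J)) {
        a <- stats::rnorm(n, 0, .cov_offset_sd)
        u <- matrix(0, n, ny)
        u[, 1] <- stats::rnorm(n, 0, .cov_sd)
        if (ny > 1) {
          e <- matrix(stats::rnorm(n * (ny - 1), 0, innov_sd), n, ny - 1)
          for (t in 2:ny) u[, t] <- .cov_ar * u[, t - 1] + e[, t - 1]
        }
        x[, , j] <- 1 + a + u
      }
    }
    eps <- matrix(stats::rnorm(n * ny, 0, config$noise_sd), n, ny)
    if (config$noise == "random_walk") {
      eps <- t(apply(eps, 1, cumsum))
    }
    miss <- if (config$missing_rate > 0) {
      stats::runif(n * ny) < config$missing_rate
    } else rep(FALSE, n * ny)
    list(pop = pop, x = x, eps = eps, miss = miss)
  })

  s_i <- stratum_of
  base_mat <- outer(config$strata$baseline[s_i], rep(1, ny)) +
    outer(config$strata$trend[s_i], years - years[1]) +
    t(cum_break)[s_i, , drop = FALSE]
  cov_term <- matrix(0, n, ny)
  if (J > 0) {
    for (j in seq_len(J)) {
      cov_term <- cov_term + config$covariate_effects[j] * out$x[, , j]
      if (!is.null(shift_mat)) {
        cov_term <- cov_term +
          (shift_mat[s_i, j] * out$x[, , j]) %*% diag(as.numeric(post))
      }
    }
  }
  y <- pmax(base_mat + cov_term + out$eps, 0)

  panel <- data.frame(
    country = rep(country, each = ny),
    year = rep(years, times = n),
    outcome = as.numeric(t(y)),
    adult_population = rep(out$pop, each = ny),
    region = rep(config$strata$region[s_i], each = ny),
    income = rep(config$strata$income[s_i], each = ny),
    oecd = rep(config$strata$oecd[s_i], each = ny),
    ratification_year = rep(cutoff + config$ratification_offsets, each = ny),
    stringsAsFactors = FALSE
  )
  if (J > 0) {
    for (j in seq_len(J)) {
      panel[[sprintf("cov_%d", j)]] <- as.numeric(t(out$x[, , j]))
    }
  }
  # missingness: uniform per country-year, never a country's first year
  miss <- matrix(out$miss, n, ny)
  miss[, 1] <- FALSE
  panel <- panel[!as.logical(t(miss)), , drop = FALSE]
  rownames(panel) <- NULL

  truth <- structure(list(
    strata = config$strata[c("name", "baseline", "trend", "level_change",
                             "slope_change")],
    covariate_effects = config$covariate_effects,
    ratification = stats::setNames(cutoff + config$ratification_offsets,
                                   country),
    stratum_of = stats::setNames(config$strata$name[s_i], country),
    intervention_year = cutoff,
    noise_sd = config$noise_sd,
    noise = config$noise,
    post_shift = shift_mat,
    seed = config$seed
  ), class = "sim_truth")

  list(panel = as_country_panel(panel), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Injected simulation truth (seed %d, %s noise, sd %.3g)\n",
              x$seed, x$noise, x$noise_sd))
  cat(sprintf("  intervention year: %d (breaks act from %d)\n",
              x$intervention_year, x$intervention_year + 1L))
  print(x$strata, row.names = FALSE)
  if (length(x$covariate_effects)) {
    cat("  covariate effects:",
        paste(signif(x$covariate_effects, 4), collapse = ", "), "\n")
  }
  if (!is.null(x$post_shift)) {
    cat("  post-cutoff covariate effect shifts (stratum x covariate):\n")
    print(x$post_shift)
  }
  invisible(x)
}

#' Write / read a simulation-truth sidecar file
#'
#' A simple `key=value` plain-text format recording every injected
#' parameter next to the emitted panel CSV, so recovery tests can reload
#' ground truth without the generating R session.
#'
#' @param truth A `sim_truth` from [generate_panel()].
#' @param path Output path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a
#'   named list of numeric/character values.
#' @export
write_truth <- function(truth, path) {
  kv <- c(
    sprintf("seed=%d", truth$seed),
    sprintf("noise=%s", truth$noise),
    sprintf("noise_sd=%.15g", truth$noise_sd),
    sprintf("intervention_year=%d", truth$intervention_year)
  )
  for (i in seq_len(nrow(truth$strata))) {
    nm <- truth$strata$name[i]
    kv <- c(kv,
            sprintf("stratum.%s.baseline=%.15g", nm, truth$strata$baseline[i]),
            sprintf("stratum.%s.trend=%.15g", nm, truth$strata$trend[i]),
            sprintf("stratum.%s.level_change=%.15g", nm,
                    truth$strata$level_change[i]),
            sprintf("stratum.%s.slope_change=%.15g", nm,
                    truth$strata$slope_change[i]))
  }
  if (length(truth$covariate_effects)) {
    kv <- c(kv, sprintf("covariate_effect.%d=%.15g",
                        seq_along(truth$covariate_effects),
                        truth$covariate_effects))
  }
  kv <- c(kv, sprintf("ratification.%s=%d", names(truth$ratification),
                      truth$ratification))
  writeLines(kv, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  suppress <- function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n) && v != "NA") v else n
  }
  stats::setNames(lapply(vals, suppress), keys)
}
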