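test_that("a constant differenced series is fit exactly with no break", {
  d <- diff_series(1984:2013, rep(6.5, 30))
  f <- fit_its(d, intervention_spec(cutoff_year = 2003),
               check_stationarity = FALSE)
  expect_equal(unname(coef(f)), c(6.5, 0, 0, 0), tolerance = 1e-9)
  expect_equal(f$n_obs, 30L)
})

test_that("an injected jump at the cutoff is recovered exactly", {
  yrs <- 1984:2013
  vals <- 5 + ifelse(yrs >= 2004, 50, 0)
  f <- fit_its(diff_series(yrs, vals), intervention_spec(cutoff_year = 2003),
               check_stationarity = FALSE)
  expect_equal(unname(coef(f)["level_change"]), 50, tolerance = 1e-9)
  expect_equal(unname(coef(f)["trend_change"]), 0, tolerance = 1e-9)

  # pure slope change: the clock is centred at the cutoff
  vals2 <- 5 + ifelse(yrs >= 2004, 2 * (yrs - 2003), 0)
  f2 <- fit_its(diff_series(yrs, vals2), intervention_spec(cutoff_year = 2003),
                check_stationarity = FALSE)
  expect_equal(unname(coef(f2)["level_change"]), 0, tolerance = 1e-9)
  expect_equal(unname(coef(f2)["trend_change"]), 2, tolerance = 1e-9)
  expect_equal(unname(coef(f2)["constant"]), 5, tolerance = 1e-9)
})

test_that("coefficients and classical SEs match the closed-form OLS oracle", {
  set.seed(2024)
  yrs <- 1990:2009
  vals <- 10 - 0.8 * (yrs - 1990) + ifelse(yrs >= 2004, 20, 0) + rnorm(20, 0, 5)
  f <- fit_its(diff_series(yrs, vals), intervention_spec(cutoff_year = 2003),
               check_stationarity = FALSE)
  o <- ols_oracle(its_design(yrs, 2003), vals)
  expect_equal(unname(coef(f)), unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(o$se), tolerance = 1e-10)
  # CIs from the t distribution with n - 4 df
  expect_equal(f$ci["level_change", "upper", "95%"],
               o$beta[3] + qt(0.975, 16) * o$se[3], tolerance = 1e-10)
})

test_that("shifting the time origin leaves the break coefficients unchanged", {
  yrs <- 1984:2013
  vals <- 3 - 0.5 * (yrs - 1984) + ifelse(yrs >= 2004, 24 + 1.7 * (yrs - 2003), 0)
  f1 <- fit_its(diff_series(yrs, vals), intervention_spec(cutoff_year = 2003),
                check_stationarity = FALSE)
  f2 <- fit_its(diff_series(yrs - 1984, vals),
                intervention_spec(cutoff_year = 2003 - 1984),
                check_stationarity = FALSE)
  expect_equal(coef(f1)[c("level_change", "trend_change")],
               coef(f2)[c("level_change", "trend_change")], tolerance = 1e-9)
  expect_equal(unname(coef(f1)["level_change"]), 24, tolerance = 1e-9)
  expect_equal(unname(coef(f1)["trend_change"]), 1.7, tolerance = 1e-9)
})

test_that("CI widths increase with the level and tiers match CI exclusion", {
  set.seed(77)
  yrs <- 1980:2013
  vals <- 8 + ifelse(yrs >= 2004, 15, 0) + rnorm(34, 0, 6)
  f <- fit_its(diff_series(yrs, vals), intervention_spec(cutoff_year = 2003),
               check_stationarity = FALSE)
  for (term in names(coef(f))) {
    w90 <- diff(f$ci[term, , "90%"])
    w95 <- diff(f$ci[term, , "95%"])
    w99 <- diff(f$ci[term, , "99%"])
    expect_true(w90 < w95 && w95 < w99)
    excl <- vapply(c("90%", "95%", "99%"), function(lv) {
      f$ci[term, "lower", lv] > 0 || f$ci[term, "upper", lv] < 0
    }, logical(1))
    expected_tier <- if (!any(excl)) 0L else max(c(90L, 95L, 99L)[excl])
    expect_identical(unname(f$tier[term]), expected_tier)
  }
})

test_that("short sides and collinear cutoffs are rejected", {
  d <- diff_series(2000:2009, rnorm(10))
  expect_error(fit_its(d, intervention_spec(cutoff_year = 2007),
                       check_stationarity = FALSE), "each side")
  expect_error(fit_its(d, intervention_spec(cutoff_year = 1990),
                       check_stationarity = FALSE), "each side")
})

test_that("a unit-root differenced series triggers the stationarity warning", {
  set.seed(5)
  d <- diff_series(1960:2013, cumsum(rnorm(54)))
  expect_warning(fit_its(d, intervention_spec(cutoff_year = 2003)),
                 "unit root")
})

test_that("Newey-West SEs are available and differ from classical on autocorrelated data", {
  set.seed(31)
  e <- as.numeric(stats::arima.sim(list(ar = 0.6), 40))
  d <- diff_series(1974:2013, 5 + e)
  fc <- fit_its(d, intervention_spec(cutoff_year = 2003),
                check_stationarity = FALSE)
  fn <- fit_its(d, intervention_spec(cutoff_year = 2003),
                se_method = "newey_west", check_stationarity = FALSE)
  expect_equal(coef(fc), coef(fn))  # point estimates identical
  expect_true(all(fn$se > 0))
  expect_false(isTRUE(all.equal(fc$se, fn$se)))
})

test_that("the suite on a single stratum equals the direct fit", {
  cfg <- sim_config(n_countries = 6, year_range = c(1980, 2013),
                    strata = one_stratum(trend = -8, level_change = 30),
                    n_covariates = 0, noise_sd = 10, missing_rate = 0,
                    seed = 13)
  p <- generate_panel(cfg)$panel
  suite <- run_its_suite(p, groupings = c("all", "income"),
                         specs = list(primary = intervention_spec()),
                         check_stationarity = FALSE)
  direct <- fit_its(first_difference(weighted_aggregate(p)),
                    intervention_spec(), check_stationarity = FALSE)
  tab <- its_table(suite)
  all_row <- tab[tab$group == "all countries", ]
  expect_equal(all_row$level_change_est, unname(coef(direct)["level_change"]))
  # one stratum: the single income group is the same series
  inc_row <- tab[tab$scheme == "income", ]
  expect_equal(inc_row$level_change_est, all_row$level_change_est)
  expect_equal(all_row$n_obs, direct$n_obs)
})

test_that("offsetting stratum breaks cancel globally but are recovered per stratum", {
  cfg <- sim_config(n_countries = 10, year_range = c(1980, 2013),
                    strata = two_strata(level_change = c(50, -50)),
                    n_covariates = 0, noise_sd = 0, missing_rate = 0,
                    seed = 17)
  p <- generate_panel(cfg)$panel
  suite <- run_its_suite(p, groupings = c("all", "region"),
                         specs = list(primary = intervention_spec()),
                         check_stationarity = FALSE)
  tab <- its_table(suite)
  expect_lt(abs(tab$level_change_est[tab$group == "all countries"]), 1e-8)
  expect_equal(tab$level_change_est[tab$group == "Europe"], 50,
               tolerance = 1e-8)
  expect_equal(tab$level_change_est[tab$group == "Asia"], -50,
               tolerance = 1e-8)
})

test_that("ratification-centred analysis equals calendar mode when all ratify at the cutoff", {
  cfg <- sim_config(n_countries = 6, year_range = c(1980, 2013),
                    strata = one_stratum(trend = -4, level_change = 20),
                    n_covariates = 0, noise_sd = 0, missing_rate = 0,
                    ratification_offsets = 0, seed = 19)
  p <- generate_panel(cfg)$panel
  cal <- fit_its(first_difference(weighted_aggregate(p)),
                 intervention_spec(cutoff_year = 2003),
                 check_stationarity = FALSE)
  ev_panel <- realign_to_event_time(p, intervention_spec("ratification_centered"),
                                    quiet = TRUE)
  ev <- fit_its(first_difference(weighted_aggregate(ev_panel)),
                intervention_spec("ratification_centered"),
                check_stationarity = FALSE)
  expect_equal(coef(cal)[c("level_change", "trend_change")],
               coef(ev)[c("level_change", "trend_change")], tolerance = 1e-9)
})

test_that("suite skips too-short groups with a reason instead of failing", {
  p <- as.data.frame(toy_panel(countries = c("A", "B"), years = 1995:2010,
                               outcome = rep(1000 - 3 * (0:15), 2)))
  p$region[p$country == "B"] <- "Asia"
  # country B observed only around the cutoff: too short on the pre side
  p <- p[!(p$country == "B" & p$year < 2001), ]
  p <- as_country_panel(p)
  suite <- suppressMessages(
    run_its_suite(p, groupings = c("all", "region"),
                  specs = list(primary = intervention_spec(cutoff_year = 2003)),
                  check_stationarity = FALSE))
  tab <- its_table(suite)
  expect_true(any(!is.na(tab$skipped)))
  expect_false(anyNA(tab$level_change_est[is.na(tab$skipped)]))
})

test_that("predict, fitted, residuals and simulate are coherent", {
  set.seed(12)
  yrs <- 1984:2013
  vals <- 5 + rnorm(30, 0, 3)
  f <- fit_its(diff_series(yrs, vals), intervention_spec(cutoff_year = 2003),
               check_stationarity = FALSE)
  expect_equal(unname(predict(f)), unname(fitted(f)), tolerance = 1e-10)
  expect_equal(unname(fitted(f) + residuals(f)), vals, tolerance = 1e-10)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30L, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
})
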