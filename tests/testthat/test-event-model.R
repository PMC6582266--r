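# shared: a small panel whose true model is outcome ~ cov_1 + year_index
event_cfg <- function(n = 6, noise_sd = 0, seed = 3, level_change = 0,
                      years = c(1990, 2010), cutoff = 2000) {
  sim_config(n_countries = n, year_range = years,
             strata = one_stratum(baseline = 1500, trend = -12,
                                  level_change = level_change),
             intervention_year = cutoff, n_covariates = 1,
             covariate_effects = 50, noise_sd = noise_sd, noise = "iid",
             missing_rate = 0, seed = seed)
}

test_that("noiseless data select the true generating specification", {
  p <- generate_panel(event_cfg())$panel
  spec <- select_spec_kfold(p, cutoff = 2000, k = 5, seed = 1, quiet = TRUE)
  expect_identical(spec$label, "covariates_trend")
  expect_lt(spec$cv_score, 1e-12)
})

test_that("a perfectly specified model yields zero gap and degenerate intervals", {
  p <- generate_panel(event_cfg())$panel
  fc <- forecast_counterfactual(p, ~ cov_1 + year_index, cutoff = 2000,
                                quiet = TRUE)
  expect_lt(max(abs(fc$table$gap)), 1e-8)
  expect_lt(max(fc$table$pi95), 1e-6)
  expect_equal(fc$table$gap, fc$table$actual - fc$table$counterfactual)
})

test_that("a constant covariate with a +200 post shift gives a gap of exactly 200", {
  p <- as.data.frame(toy_panel(countries = c("A", "B", "C"),
                               years = 1990:2009, outcome = 500))
  p$cov_1 <- 1  # aliased with the intercept: the fit must drop it gracefully
  p$outcome[p$year >= 2001] <- 700
  p <- as_country_panel(p)
  fc <- suppressWarnings(
    forecast_counterfactual(p, ~ cov_1, cutoff = 2000, quiet = TRUE))
  expect_equal(fc$table$gap, rep(200, 9), tolerance = 1e-9)
  expect_equal(fc$table$counterfactual, rep(500, 9), tolerance = 1e-9)
})

test_that("k-fold selection matches an independently coded CV loop", {
  p <- generate_panel(event_cfg(n = 5, noise_sd = 40, seed = 8,
                                years = c(1990, 2005)))$panel
  cands <- list(small = ~ cov_1, true = ~ cov_1 + year_index)
  spec <- select_spec_kfold(p, cands, cutoff = 2003, k = 5, seed = 99,
                            quiet = TRUE)

  # brute-force oracle: same reproducible folds, hand-rolled per-fold OLS
  d <- as.data.frame(p)
  d$year_index <- d$year - min(d$year)
  pre <- d[d$year <= 2003, ]
  set.seed(99)
  folds <- sample(rep_len(1:5, nrow(pre)))
  cv_mse <- function(X, y) {
    err <- numeric(length(y))
    for (f in 1:5) {
      o <- ols_oracle(X[folds != f, , drop = FALSE], y[folds != f])
      err[folds == f] <- y[folds == f] -
        X[folds == f, , drop = FALSE] %*% o$beta
    }
    mean(err^2)
  }
  mse_small <- cv_mse(cbind(1, pre$cov_1), pre$outcome)
  mse_true <- cv_mse(cbind(1, pre$cov_1, pre$year_index), pre$outcome)
  expect_equal(spec$cv_score, min(mse_small, mse_true), tolerance = 1e-10)
  expect_identical(spec$label, if (mse_true < mse_small) "true" else "small")
})

test_that("k equal to n reproduces the leave-one-out residual identity", {
  p <- generate_panel(event_cfg(n = 1, noise_sd = 25, seed = 4,
                                years = c(1990, 2005)))$panel
  pre_n <- sum(p$year <= 2003)
  spec <- select_spec_kfold(p, list(m = ~ cov_1), cutoff = 2003, k = pre_n,
                            seed = 2, quiet = TRUE)
  d <- as.data.frame(p)
  pre <- d[d$year <= 2003, ]
  fit <- lm(outcome ~ cov_1, data = pre)
  loo <- residuals(fit) / (1 - hatvalues(fit))
  expect_equal(spec$cv_score, mean(loo^2), tolerance = 1e-10)
})

test_that("post-cutoff outcomes never leak into the pre-cutoff fit", {
  p <- generate_panel(event_cfg(n = 6, noise_sd = 30, seed = 6))$panel
  fc1 <- forecast_counterfactual(p, ~ cov_1 + year_index, cutoff = 2000,
                                 quiet = TRUE)
  tampered <- as.data.frame(p)
  tampered$outcome[tampered$year >= 2001] <-
    tampered$outcome[tampered$year >= 2001] + 1000
  fc2 <- forecast_counterfactual(as_country_panel(tampered),
                                 ~ cov_1 + year_index, cutoff = 2000,
                                 quiet = TRUE)
  expect_identical(coef(fc1), coef(fc2))
  expect_equal(fc1$table$counterfactual, fc2$table$counterfactual,
               tolerance = 1e-12)
  expect_equal(fc2$table$gap, fc1$table$gap + 1000, tolerance = 1e-9)
})

test_that("the aggregate counterfactual is invariant under population rescaling", {
  p <- generate_panel(sim_config(n_countries = 8, seed = 14,
                                 n_covariates = 1, covariate_effects = 50,
                                 noise = "iid", missing_rate = 0))$panel
  fc1 <- forecast_counterfactual(p, ~ cov_1 + year_index, quiet = TRUE)
  p2 <- as.data.frame(p)
  p2$adult_population <- p2$adult_population * 0.37
  fc2 <- forecast_counterfactual(as_country_panel(p2), ~ cov_1 + year_index,
                                 quiet = TRUE)
  expect_equal(fc1$table, fc2$table, tolerance = 1e-10)
})

test_that("prediction-interval half-widths are ordered and scale with noise", {
  widths <- sapply(1:6, function(seed) {
    w <- numeric(2)
    for (i in 1:2) {
      p <- generate_panel(event_cfg(n = 10, noise_sd = 20 * i, seed = seed))$panel
      fc <- forecast_counterfactual(p, ~ cov_1 + year_index, cutoff = 2000,
                                    quiet = TRUE)
      expect_true(all(fc$table$pi80 < fc$table$pi90 &
                        fc$table$pi90 < fc$table$pi95))
      w[i] <- mean(fc$table$pi95)
    }
    w[2] / w[1]
  })
  expect_gt(mean(widths), 1.8)
  expect_lt(mean(widths), 2.2)
})

test_that("countries with missing covariates are excluded as complete cases", {
  p <- as.data.frame(generate_panel(event_cfg(n = 5))$panel)
  p$cov_1[p$country == "C03" & p$year == 1995] <- NA
  p <- as_country_panel(p)
  # oracle: countries whose covariate record is complete
  cc <- names(which(tapply(!is.na(p$cov_1), p$country, all)))
  expect_message(
    spec <- select_spec_kfold(p, list(m = ~ cov_1 + year_index),
                              cutoff = 2000, k = 5, seed = 1),
    "C03")
  expect_identical(spec$excluded_countries, "C03")
  fc <- forecast_counterfactual(p, ~ cov_1 + year_index, cutoff = 2000,
                                quiet = TRUE)
  expect_setequal(fc$countries, cc)
})

test_that("selection requires a seed and survives rank-deficient candidates", {
  p <- generate_panel(event_cfg())$panel
  expect_error(select_spec_kfold(p, cutoff = 2000, k = 5), "seed")
  p2 <- as.data.frame(p)
  p2$cov_2 <- p2$cov_1  # perfectly collinear candidate
  p2 <- as_country_panel(p2)
  expect_warning(
    spec <- select_spec_kfold(p2, list(dup = ~ cov_1 + cov_2,
                                       ok = ~ cov_1 + year_index),
                              cutoff = 2000, k = 5, seed = 1, quiet = TRUE),
    "rank-deficient")
  expect_identical(spec$label, "ok")
})

test_that("the event suite matches single fits and honours its variants", {
  p <- generate_panel(event_cfg(n = 6, noise_sd = 15, seed = 10))$panel
  suite <- run_event_suite(p, cutoff = 2000, spec = ~ cov_1 + year_index,
                           groupings = c("all", "income"),
                           variants = c("base", "unweighted"),
                           exclude = list(largest = "C01"))
  tab <- forecast_table(suite)
  expect_setequal(unique(tab$variant),
                  c("base", "unweighted", "excluding largest"))
  g_base <- tab[tab$scheme == "all" & tab$variant == "base", ]
  g_unw <- tab[tab$scheme == "all" & tab$variant == "unweighted", ]
  # equal populations: weighted and unweighted identical
  expect_equal(g_base$gap, g_unw$gap, tolerance = 1e-10)
  # one stratum: the income group is the global series
  i_base <- tab[tab$scheme == "income" & tab$variant == "base", ]
  expect_equal(i_base$gap, g_base$gap, tolerance = 1e-10)
  # the exclusion variant drops a country
  excl <- suite[[which(vapply(suite, function(r)
    identical(r$variant, "excluding largest"), logical(1)))]]
  expect_false("C01" %in% excl$forecast$countries)
})

test_that("distributed covariate lags extend the specification, never the outcome", {
  p <- generate_panel(event_cfg(n = 6, noise_sd = 10, seed = 11))$panel
  spec <- select_spec_kfold(p, list(m = ~ cov_1 + year_index), cutoff = 2000,
                            k = 5, seed = 1, quiet = TRUE)
  lag2 <- add_spec_lags(spec, 2)
  expect_true(all(c("cov_1_lag1", "cov_1_lag2") %in% all.vars(lag2$formula)))
  expect_false("outcome" %in% all.vars(lag2$formula))
  fc <- forecast_counterfactual(p, lag2, cutoff = 2000, quiet = TRUE)
  expect_equal(nrow(fc$table), 10L)
  # lagged columns line up within country on calendar year
  d <- prepare_event_data(p, lags = 1)
  i <- which(d$country == "C02" & d$year == 1995)
  j <- which(d$country == "C02" & d$year == 1994)
  expect_equal(d$cov_1_lag1[i], d$cov_1[j])
})
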