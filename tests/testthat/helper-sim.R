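# Shared fixture builders: tiny strata specs and hand-made panels.

# single-stratum spec with degenerate population range (equal weights)
one_stratum <- function(baseline = 1000, trend = -12, level_change = 0,
                        slope_change = 0, pop = 1e6, name = "s1",
                        region = "Europe", income = "High income",
                        oecd = TRUE) {
  data.frame(name = name, baseline = baseline, trend = trend,
             level_change = level_change, slope_change = slope_change,
             pop_min = pop, pop_max = pop, region = region, income = income,
             oecd = oecd, stringsAsFactors = FALSE)
}

two_strata <- function(level_change = c(0, 0), slope_change = c(0, 0),
                       trend = c(-12, -12), baseline = c(1500, 1500),
                       pop = 1e6) {
  rbind(
    one_stratum(baseline[1], trend[1], level_change[1], slope_change[1],
                pop = pop, name = "sA", region = "Europe",
                income = "High income", oecd = TRUE),
    one_stratum(baseline[2], trend[2], level_change[2], slope_change[2],
                pop = pop, name = "sB", region = "Asia",
                income = "Low and middle income", oecd = FALSE)
  )
}

# a small hand-built panel: `n` countries, equal populations unless given
toy_panel <- function(countries = c("France", "Germany", "Japan"),
                      years = 1995:2010, outcome = 1000,
                      population = 1e6, region = "Europe",
                      income = "High income", oecd = TRUE,
                      ratification_year = 2005L) {
  grid <- data.frame(country = rep(countries, each = length(years)),
                     year = rep(years, times = length(countries)),
                     stringsAsFactors = FALSE)
  grid$outcome <- rep_len(outcome, nrow(grid))
  grid$adult_population <- rep_len(population, nrow(grid))
  grid$region <- rep_len(region, nrow(grid))
  grid$income <- rep_len(income, nrow(grid))
  grid$oecd <- rep_len(oecd, nrow(grid))
  grid$ratification_year <- rep(rep_len(ratification_year, length(countries)),
                                each = length(years))
  as_country_panel(grid)
}

# differenced-series fixture directly from values
diff_series <- function(years, values, label = "fixture") {
  aggregate_series(years, values, label = label, differenced = TRUE)
}

# closed-form OLS oracle: coefficients and classical SEs from (X'X)^-1 X'y
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = unname(drop(beta)), se = unname(sqrt(diag(s2 * XtX_inv))),
       sigma2 = s2)
}

# ITS design matrix matching the package's parameterisation
its_design <- function(time, cutoff) {
  post <- as.numeric(time >= cutoff + 1)
  cbind(1, time - time[1], post, (time - cutoff) * post)
}
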