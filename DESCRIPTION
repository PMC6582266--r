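Package: itsevent
Title: Interrupted Time Series and In-Sample Forecast Event Models for
    Global Policy Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quasi-experimental evaluation of dated global interventions on
    population-weighted country-year outcomes, with cigarette consumption
    per adult as the motivating application.  Implements segmented
    regression on first-differenced aggregate series (interrupted time
    series with level-change and trend-change estimates at 90/95/99%
    confidence), Dickey-Fuller unit-root checks against finite-sample
    critical values, counterfactual in-sample forecast event models with
    k-fold cross-validated specification search and 80/90/95% prediction
    intervals, population-weighted aggregation, treaty-ratification
    event-time realignment, robustness-check suites, and a synthetic
    country-year panel generator with known injected effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
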