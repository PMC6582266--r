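#' Country-year panel of per-adult consumption
#'
#' The central data container: a long-format data frame with one row per
#' (country, year) holding the outcome (cigarettes consumed per adult aged
#' 15 or older per year), the adult population used as the aggregation
#' weight, group labels (UN region, income tier, OECD membership), each
#' country's treaty ratification year (NA when not ratified) and any number
#' of `cov_*` covariate columns (economic, political, tobacco-industry and
#' human-development indicators).
#'
#' `as_country_panel()` validates a plain data frame and stamps the class;
#' `validate_panel()` re-checks an existing object and reports every
#' violated invariant with the offending row numbers.
#'
#' Invariants enforced:
#' * `(country, year)` pairs are unique;
#' * `outcome >= 0`, `adult_population > 0`;
#' * group labels are constant within a country across years.
#'
#' @param x A data frame with columns `country`, `year`, `outcome`,
#'   `adult_population`, `region`, `income`, `oecd`, `ratification_year`
#'   and optionally `cov_*` columns. Missing covariate cells are `NA`
#'   (absent), never zero.
#' @return A `country_panel` object (a validated data frame).
#' @seealso [read_panel()], [write_panel()], [weighted_aggregate()]
#' @export
as_country_panel <- function(x, line_offset = NULL) {
  if (!is.data.frame(x)) fail("panel must be a data frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("country", "year", "outcome", "adult_population",
                "region", "income", "oecd", "ratification_year")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    fail("panel is missing required column(s): %s",
         paste(missing_cols, collapse = ", "))
  }
  x$country <- as.character(x$country)
  x$year <- as.integer(x$year)
  x$oecd <- as.logical(x$oecd)
  x$ratification_year <- as.integer(x$ratification_year)
  class(x) <- c("country_panel", "data.frame")
  validate_panel(x, line_offset = line_offset)  # input order: row ids match file
  x <- x[order(x$country, x$year), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("country_panel", "data.frame")
  x
}

#' @rdname as_country_panel
#' @param panel A `country_panel` (or coercible data frame).
#' @param line_offset When validating a freshly read file, the number of
#'   header lines, so violations are reported with file line numbers;
#'   `NULL` reports data-frame row numbers.
#' @export
validate_panel <- function(panel, line_offset = NULL) {
  problems <- character(0)
  row_id <- function(i) {
    if (is.null(line_offset)) paste0("row ", i)
    else paste0("line ", i + line_offset)
  }

  dup <- duplicated(panel[c("country", "year")])
  if (any(dup)) {
    for (i in which(dup)) {
      problems <- c(problems, sprintf(
        "duplicate (country, year) pair (%s, %d) at %s",
        panel$country[i], panel$year[i], row_id(i)))
    }
  }
  bad_pop <- which(!is.finite(panel$adult_population) |
                     panel$adult_population <= 0)
  for (i in bad_pop) {
    problems <- c(problems, sprintf(
      "non-positive adult_population for (%s, %d) at %s",
      panel$country[i], panel$year[i], row_id(i)))
  }
  bad_out <- which(is.finite(panel$outcome) & panel$outcome < 0)
  for (i in bad_out) {
    problems <- c(problems, sprintf(
      "negative outcome for (%s, %d) at %s",
      panel$country[i], panel$year[i], row_id(i)))
  }
  # strata labels constant within country
  for (lab in c("region", "income", "oecd", "ratification_year")) {
    n_lab <- tapply(panel[[lab]], panel$country,
                    function(v) length(unique(v)))
    varying <- names(n_lab)[n_lab > 1]
    if (length(varying)) {
      problems <- c(problems, sprintf(
        "label '%s' varies within country: %s",
        lab, paste(varying, collapse = ", ")))
    }
  }
  if (length(problems)) {
    fail("invalid panel:\n%s", paste("  -", problems, collapse = "\n"))
  }
  invisible(panel)
}

#' Names of the covariate columns of a panel
#' @param panel A `country_panel`.
#' @return Character vector of `cov_*` column names (possibly empty).
#' @export
covariate_names <- function(panel) {
  grep("^cov_", names(panel), value = TRUE)
}

#' Read and write country-year panel files
#'
#' The on-disk schema is a delimited text file (comma or tab; the delimiter
#' is detected from the header line) with header
#' `country,year,outcome,adult_population,region,income,oecd,ratification_year,cov_*`.
#' The writer always emits comma-delimited UTF-8. Empty covariate and
#' ratification cells are read as `NA` (absent), never as zero. Rows
#' violating panel invariants are reported with their file line numbers.
#'
#' @param path Path to a delimited text file with a header row.
#' @return `read_panel()` returns a validated [as_country_panel()] object;
#'   `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) fail("panel file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          fileEncoding = "UTF-8", check.names = FALSE)
  tryCatch(as_country_panel(df, line_offset = 1L),
           error = function(e) fail("while reading %s: %s", path,
                                    conditionMessage(e)))
}

#' @rdname read_panel
#' @param panel A `country_panel`.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Remove named countries from a panel
#'
#' Robustness checks drop China or the set of countries that split since
#' the start of the observation window; this helper removes any named
#' countries and logs the removal.
#'
#' @param panel A `country_panel`.
#' @param countries Character vector of country identifiers to drop, or a
#'   predicate function over country names returning `TRUE` to drop.
#' @param quiet Suppress the removal message.
#' @return The reduced `country_panel`; warns if nothing remains.
#' @export
exclude_countries <- function(panel, countries, quiet = FALSE) {
  validate_panel(panel)
  all_countries <- unique(panel$country)
  drop <- if (is.function(countries)) {
    all_countries[vapply(all_countries, countries, logical(1))]
  } else {
    intersect(all_countries, as.character(countries))
  }
  if (!length(drop)) return(panel)
  out <- panel[!panel$country %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet) {
    message(sprintf("excluded %d country(ies): %s", length(drop),
                    paste(sort(drop), collapse = ", ")))
  }
  if (!nrow(out)) warning("exclusion removed every country", call. = FALSE)
  class(out) <- c("country_panel", "data.frame")
  out
}

#' Specify the intervention point
#'
#' An intervention is either a calendar cutoff year (the treaty's adoption
#' year 2003 as the primary point, 1999 — the start of negotiations — as a
#' secondary point) or ratification-centred: each country's series is
#' re-indexed to event time relative to its own ratification year, with
#' T0 = 0 at ratification.
#'
#' Throughout the package the post-intervention period starts the year
#' AFTER the cutoff: a 2003 cutoff means discontinuities are evaluated from
#' 2004 onwards, and the cutoff-year observation belongs to the pre period.
#'
#' @param mode `"calendar"` or `"ratification_centered"`.
#' @param cutoff_year Calendar cutoff (calendar mode). In
#'   ratification-centred mode the cutoff is event time 0.
#' @param window Optional length-2 integer vector of event-time bounds
#'   (e.g. `c(-3, 3)`) applied by [realign_to_event_time()].
#' @return An `intervention_spec` object.
#' @export
intervention_spec <- function(mode = c("calendar", "ratification_centered"),
                              cutoff_year = 2003, window = NULL) {
  mode <- match.arg(mode)
  if (mode == "calendar" && !is_year(cutoff_year)) {
    fail("cutoff_year must be a single calendar year")
  }
  if (!is.null(window)) {
    if (length(window) != 2L || any(window != round(window)) ||
        window[1] > window[2]) {
      fail("window must be an ordered integer pair, e.g. c(-3, 3)")
    }
    window <- as.integer(window)
  }
  structure(list(mode = mode,
                 cutoff_year = if (mode == "calendar") as.integer(cutoff_year)
                               else 0L,
                 window = window),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("Intervention point:",
      if (x$mode == "calendar")
        sprintf("calendar year %d (post period from %d)", x$cutoff_year,
                x$cutoff_year + 1L)
      else "ratification-centred (T0 = each country's ratification year)",
      "\n")
  if (!is.null(x$window)) {
    cat(sprintf("  event-time window: [%d, %d]\n", x$window[1], x$window[2]))
  }
  invisible(x)
}

#' Re-index a panel to treaty-ratification event time
#'
#' Each included country's calendar years are mapped to integer event time
#' `year - ratification_year`, so that T0 is the year the treaty became
#' binding on that country. Countries without a ratification year are
#' excluded (and reported); an optional window keeps only event times
#' within the stated bounds. No row is created or duplicated — the map is a
#' bijection on the surviving rows.
#'
#' @param panel A `country_panel`.
#' @param spec An [intervention_spec()] with `mode = "ratification_centered"`.
#' @param quiet Suppress the exclusion message.
#' @return A `country_panel` whose `year` column is event time.
#' @export
realign_to_event_time <- function(panel, spec, quiet = FALSE) {
  validate_panel(panel)
  if (!inherits(spec, "intervention_spec") ||
      spec$mode != "ratification_centered") {
    fail("realign_to_event_time() needs a ratification_centered intervention_spec")
  }
  has_rat <- !is.na(panel$ratification_year)
  if (!any(has_rat)) fail("no country has a ratification year")
  dropped <- unique(panel$country[!has_rat])
  if (length(dropped) && !quiet) {
    message(sprintf("excluded %d country(ies) without a ratification year: %s",
                    length(dropped), paste(sort(dropped), collapse = ", ")))
  }
  out <- panel[has_rat, , drop = FALSE]
  out$year <- out$year - out$ratification_year
  if (!is.null(spec$window)) {
    out <- out[out$year >= spec$window[1] & out$year <= spec$window[2], ,
               drop = FALSE]
  }
  if (!nrow(out)) fail("no observations survive the event-time window")
  out <- out[order(out$country, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("country_panel", "data.frame")
  out
}

#' @export
print.country_panel <- function(x, ...) {
  cat(sprintf(
    "Country-year panel: %d countries, years %d-%d, %d rows, %d covariate(s)\n",
    length(unique(x$country)), min(x$year), max(x$year), nrow(x),
    length(covariate_names(x))))
  NextMethod()
}
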