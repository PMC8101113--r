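#' County-level covariate columns recognised by the package
#'
#' Socio-demographic covariates carried by the bundled Georgia table and
#' recognised by [fit_bym()]: percentages are on the 0--100 scale, income in
#' USD.
#'
#' @return Character vector of column names.
#' @export
county_covariates <- function() {
  c("pct_65plus", "pct_black", "pct_bachelors", "pct_poverty",
    "pct_foreign_born", "pct_rural", "pct_unemployed", "median_family_income")
}

#' Load and validate a county incidence table
#'
#' Reads a CSV of county-level case counts and populations (plus optional
#' covariate columns), validates it, and recomputes the crude incidence rate
#' from `cases` and `population` rather than trusting any rate column in the
#' file. Blank cells or `"."` are treated as missing; missingness in covariate
#' columns is preserved (see [summarize_table()] and the imputation policy in
#' [fit_bym()]).
#'
#' The token `"georgia_2012_2016"` loads the bundled transcription of
#' published Georgia county characteristics and prostate cancer incidence,
#' 2012--2016 (159 counties; `cases` holds *mean annual* cases, so the
#' modelled period count is `cases_period = round(cases * period_years)` with
#' `period_years = 5`).
#'
#' @param path Path to a CSV file, or the fixture token
#'   `"georgia_2012_2016"`.
#' @param period_years Number of years the case column is averaged over; the
#'   derived period total `cases_period = round(cases * period_years)` is the
#'   count entering the Poisson model. Defaults to 5 for the bundled fixture
#'   and 1 otherwise.
#' @return A `county_table`: a [tibble][tibble::tibble] with columns
#'   `area_id`, `cases`, `population`, `crude_rate` (per 100,000, recomputed),
#'   `cases_period`, and any covariate columns present, with attributes
#'   `period_years` and `source_label`.
#' @examples
#' ga <- load_county_table("georgia_2012_2016")
#' nrow(ga)   # 159 counties
#' @export
load_county_table <- function(path, period_years = NULL) {
  source_label <- path
  if (identical(path, "georgia_2012_2016")) {
    path <- system.file("extdata", "georgia_2012_2016.csv",
                        package = "bymrisk", mustWork = TRUE)
    period_years <- period_years %||% 5
  }
  period_years <- period_years %||% 1
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  d <- readr::read_csv(path, na = c("", ".", "NA"), show_col_types = FALSE,
                       progress = FALSE)
  required <- c("area_id", "cases", "population")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  d$area_id <- as.character(d$area_id)
  new_county_table(d, period_years = period_years, source_label = source_label)
}

#' Construct and validate a county table from a data frame
#'
#' @param data Data frame with at least `area_id`, `cases`, `population`.
#' @param period_years Years spanned by the (annualised) case column.
#' @param source_label Provenance string stored as an attribute.
#' @return A validated `county_table` tibble (see [load_county_table()]).
#' @export
new_county_table <- function(data, period_years = 1, source_label = "data") {
  d <- tibble::as_tibble(data)
  if (nrow(d) == 0L) abort("county table is empty")
  if (anyDuplicated(d$area_id)) {
    dup <- unique(d$area_id[duplicated(d$area_id)])
    abort(paste0("duplicate area_id: ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(d$population)) || any(d$population <= 0)) {
    bad <- d$area_id[is.na(d$population) | d$population <= 0]
    abort(paste0("non-positive population for: ", paste(bad, collapse = ", ")))
  }
  if (any(is.na(d$cases)) || any(d$cases < 0)) {
    bad <- d$area_id[is.na(d$cases) | d$cases < 0]
    abort(paste0("negative or missing cases for: ", paste(bad, collapse = ", ")))
  }
  pct <- intersect(setdiff(county_covariates(), "median_family_income"), names(d))
  for (cc in pct) {
    v <- d[[cc]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      abort(paste0(cc, " outside [0, 100]"))
    }
  }
  d$crude_rate <- crude_rate(d$cases, d$population)
  d$cases_period <- round(d$cases * period_years)
  structure(d,
            class = c("county_table", class(tibble::tibble()))  ,
            period_years = period_years,
            source_label = source_label)
}

#' Crude incidence rate per 100,000
#'
#' @param cases Non-negative case counts.
#' @param population Positive populations at risk.
#' @return `cases / population * 1e5`. Unrounded; round for presentation.
#' @examples
#' crude_rate(22, 9159)   # 240.2 per 100,000
#' @export
crude_rate <- function(cases, population) {
  if (any(population <= 0)) abort("population must be positive")
  if (any(cases < 0)) abort("cases must be non-negative")
  cases / population * 1e5
}

#' Expected counts by internal (indirect) standardization
#'
#' Fills the expected count \eqn{E_i = \mathrm{pop}_i \times \sum_j Y_j /
#' \sum_j \mathrm{pop}_j}, the count each area would see under the pooled
#' study rate. By construction \eqn{\sum_i E_i = \sum_i Y_i} exactly.
#'
#' @param data A `county_table` (or data frame with `population` and the
#'   count column).
#' @param count_col Column holding the modelled count; defaults to
#'   `cases_period` when present, else `cases`.
#' @return `data` with an `expected` column added.
#' @export
compute_expected_counts <- function(data, count_col = NULL) {
  if (nrow(data) == 0L) abort("county table is empty")
  count_col <- count_col %||%
    (if ("cases_period" %in% names(data)) "cases_period" else "cases")
  y <- data[[count_col]]
  pooled <- sum(y) / sum(data$population)
  dplyr::mutate(data, expected = .data$population * pooled)
}

#' Add the standardized morbidity ratio (SMR)
#'
#' The raw, unsmoothed relative risk \eqn{Y_i / E_i}. Under internal
#' standardization the expected-count-weighted mean SMR is exactly 1.
#'
#' @inheritParams compute_expected_counts
#' @return `data` with an `smr` column added.
#' @export
add_smr <- function(data, count_col = NULL) {
  if (!"expected" %in% names(data)) {
    abort("run compute_expected_counts() first (no `expected` column)")
  }
  if (any(data$expected <= 0)) abort("expected counts must be positive")
  count_col <- count_col %||%
    (if ("cases_period" %in% names(data)) "cases_period" else "cases")
  dplyr::mutate(data, smr = .data[[count_col]] / .data$expected)
}

#' Table-1-style column summaries
#'
#' Unweighted means over non-missing values for each percentage covariate and
#' for `cases`, `population` and `crude_rate`; for `median_family_income`
#' (already a county-level median) the cross-county mean is reported, which is
#' how the bundled Georgia table's "All" row summarizes income. Missing-value
#' counts are reported per column.
#'
#' @param data A `county_table`.
#' @return A tibble with columns `variable`, `statistic`, `value`,
#'   `n_missing`.
#' @examples
#' summarize_table(load_county_table("georgia_2012_2016"))
#' @export
summarize_table <- function(data) {
  if (nrow(data) == 0L) abort("county table is empty")
  vars <- intersect(c(county_covariates(), "cases", "population", "crude_rate"),
                    names(data))
  purrr::map_dfr(vars, function(vn) {
    v <- data[[vn]]
    stat <- if (vn == "median_family_income") "mean_of_county_medians" else "mean"
    tibble::tibble(variable = vn, statistic = stat,
                   value = mean(v, na.rm = TRUE),
                   n_missing = sum(is.na(v)))
  })
}

#' Write a county table to CSV
#'
#' Missing covariate cells are written blank, so
#' `load_county_table(write_county_table(x, f))` round-trips values and
#' missingness.
#'
#' @param data A `county_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_county_table <- function(data, path) {
  out <- dplyr::select(as_tibble(data), -dplyr::any_of("cases_period"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @export
print.county_table <- function(x, ...) {
  cat(sprintf("# county_table: %d areas, period_years = %s (%s)\n",
              nrow(x), attr(x, "period_years"), attr(x, "source_label")))
  NextMethod()
}
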