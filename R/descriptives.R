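#' Aggregate growth rate of a staffing category
#'
#' Percentage change of the summed headcount over a region set between two
#' years: `(sum(count[year1]) - sum(count[year0])) / sum(count[year0]) x
#' 100`, reported at 2 decimals (half-up). Invariant to the count unit.
#'
#' @param x An `equipanel_panel` (city-level panels are aggregated to
#'   provinces first).
#' @param category Personnel category.
#' @param year0,year1 Baseline and comparison year.
#' @param scope Provinces to include; default: all provinces in the panel.
#' @return Growth rate in percent, rounded to 2 decimals.
#' @examples
#' growth_rate(yrd_panel(), "health_technician", 2014, 2022)
#' @export
growth_rate <- function(x, category, year0, year1, scope = NULL) {
  validate_panel(x)
  if (x$level == "city") x <- aggregate_to_province(x)
  scope <- scope %||% sort(unique(x$resources$province))
  res <- x$resources[x$resources$category == category &
                       x$resources$province %in% scope, ]
  sum_year <- function(yr) {
    sub <- res[res$year == yr, ]
    missing <- setdiff(scope, sub$province)
    if (length(missing) > 0) {
      stop_coverage(sprintf("no %s record for %s in %d", category,
                            paste(missing, collapse = ", "), yr))
    }
    sum(sub$count)
  }
  base <- sum_year(year0)
  if (base <= 0) stop_domain("baseline total must be > 0")
  round_half_up((sum_year(year1) - base) / base * 100, 2)
}

#' Physician-to-nurse ("healthcare") ratio
#'
#' The staffing-structure indicator `1:x` with `x = nurses / physicians`
#' rounded half-up to 2 decimals; national planning targets call for 1:2.
#'
#' @param physicians Licensed (assistant) physician headcount, `> 0`.
#' @param nurses Registered nurse headcount.
#' @return Character vector like `"1:1.06"`.
#' @examples
#' healthcare_ratio(17.86, 18.88)
#' @export
healthcare_ratio <- function(physicians, nurses) {
  if (anyNA(c(physicians, nurses))) stop_domain("missing headcount")
  if (any(physicians <= 0)) stop_domain("physician headcount must be > 0")
  sprintf("1:%.2f", round_half_up(nurses / physicians, 2))
}

#' Staffing rate per 10,000 population
#'
#' @param count Headcount (persons).
#' @param population Resident population (persons), `> 0`.
#' @return Staff per 10,000 residents, full precision.
#' @examples
#' per_10k(458500, 85050000)
#' @export
per_10k <- function(count, population) {
  if (anyNA(c(count, population))) stop_domain("missing count or population")
  if (any(population <= 0)) stop_domain("population must be > 0")
  count / population * 1e4
}

#' Descriptive staffing table
#'
#' Province x year table of headcounts by category (in the requested unit)
#' plus the healthcare ratio, the shape of published yearbook summaries.
#'
#' @param x An `equipanel_panel`; city-level panels are aggregated to
#'   provinces.
#' @param unit Output unit for counts: `"wan"` (10,000 persons, yearbook
#'   style, default) or `"persons"`.
#' @return Tibble with one row per province x year: counts per category
#'   (wide) and `healthcare_ratio`.
#' @examples
#' head(descriptive_table(yrd_panel()))
#' @export
descriptive_table <- function(x, unit = c("wan", "persons")) {
  unit <- match.arg(unit)
  validate_panel(x)
  if (x$level == "city") x <- aggregate_to_province(x)
  res <- x$resources
  if (unit == "wan") res$count <- res$count / 1e4
  wide <- tidyr::pivot_wider(res[c("province", "year", "category", "count")],
                             names_from = "category", values_from = "count")
  if (all(c("licensed_physician", "registered_nurse") %in% names(wide))) {
    wide$healthcare_ratio <- healthcare_ratio(wide$licensed_physician,
                                              wide$registered_nurse)
  }
  dplyr::arrange(wide, .data$province, .data$year)
}
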