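#' Health resource agglomeration degree (HRAD)
#'
#' Ratio of a region's health-personnel density to the reference region's:
#' `HRAD_i = (HR_i / A_i) / (HR_n / A_n)`. A value of 1 means the region
#' holds health personnel exactly in proportion to its land area; above 1,
#' resources are geographically concentrated there.
#'
#' @param hr_i Regional headcount (persons), `>= 0`.
#' @param a_i Regional land area (km2), `> 0`.
#' @param hr_n Reference headcount, `> 0`.
#' @param a_n Reference land area, `> 0`.
#' @return HRAD value(s), dimensionless and `>= 0`.
#' @examples
#' hrad(30, 10, 100, 100)
#' @export
hrad <- function(hr_i, a_i, hr_n, a_n) {
  check_agg_args(hr_i, a_i, hr_n, a_n, "headcount")
  (hr_i / a_i) / (hr_n / a_n)
}

#' Population agglomeration degree (PAD)
#'
#' `PAD_i = (P_i / A_i) / (P_n / A_n)`: the region's population density
#' relative to the reference region's.
#'
#' @param p_i Regional resident population (persons), `>= 0`.
#' @param a_i Regional land area (km2), `> 0`.
#' @param p_n Reference population, `> 0`.
#' @param a_n Reference land area, `> 0`.
#' @return PAD value(s), dimensionless and `>= 0`.
#' @examples
#' pad(20, 10, 100, 100)
#' @export
pad <- function(p_i, a_i, p_n, a_n) {
  check_agg_args(p_i, a_i, p_n, a_n, "population")
  (p_i / a_i) / (p_n / a_n)
}

check_agg_args <- function(num_i, a_i, num_n, a_n, what) {
  if (anyNA(c(num_i, a_i, num_n, a_n))) stop_domain("missing value in agglomeration inputs")
  if (any(a_i <= 0) || any(a_n <= 0)) stop_domain("areas must be > 0")
  if (any(num_n <= 0)) stop_domain(sprintf("reference %s must be > 0", what))
  if (any(num_i < 0)) stop_domain(sprintf("regional %s must be >= 0", what))
  if (any(num_i > num_n + 1e-9 * num_n) || any(a_i > a_n * (1 + 1e-9))) {
    stop_domain("region must be contained in the reference region")
  }
  invisible(NULL)
}

#' HRAD over PAD
#'
#' `HRAD_i / PAD_i`, algebraically the region's per-capita resource level
#' relative to the reference (`(HR_i / P_i) / (HR_n / P_n)`): 1 means
#' resources match the population's share exactly.
#'
#' @param hrad HRAD value(s), `>= 0`.
#' @param pad PAD value(s), `> 0`.
#' @return The ratio, dimensionless.
#' @examples
#' hrad_pad_ratio(0.923, 0.781)
#' @export
hrad_pad_ratio <- function(hrad, pad) {
  if (anyNA(c(hrad, pad))) stop_domain("missing HRAD or PAD value")
  if (any(pad <= 0)) stop_domain("PAD must be > 0")
  if (any(hrad < 0)) stop_domain("HRAD must be >= 0")
  hrad / pad
}

#' Equity verdicts from agglomeration degrees
#'
#' Geographic verdict from HRAD and population verdict from HRAD/PAD, each
#' on the same rule: above 1 the region is `"better"` provisioned than
#' proportional, exactly 1 (tolerance 1e-9) is `"absolute"` equity, below 1
#' is `"worse"`.
#'
#' @param hrad HRAD value(s).
#' @param ratio HRAD/PAD value(s).
#' @param tol Equality tolerance for the "= 1" verdict.
#' @return Tibble with columns `geo_verdict` and `pop_verdict`, each one of
#'   `"better"`, `"absolute"`, `"worse"`.
#' @examples
#' classify_agglomeration(0.923, 1.182)
#' @export
classify_agglomeration <- function(hrad, ratio, tol = 1e-9) {
  if (anyNA(c(hrad, ratio)) || any(!is.finite(c(hrad, ratio)))) {
    stop_domain("HRAD and ratio must be finite")
  }
  if (any(c(hrad, ratio) < 0)) stop_domain("HRAD and ratio must be >= 0")
  verdict <- function(v) {
    ifelse(abs(v - 1) <= tol, "absolute", ifelse(v > 1, "better", "worse"))
  }
  tibble::tibble(geo_verdict = verdict(hrad), pop_verdict = verdict(ratio))
}

#' Agglomeration table from a panel
#'
#' Per year, category and province: HRAD, PAD, their ratio, and the equity
#' verdicts, against a configurable reference region. By default the
#' reference is the union of all regions in the panel (the panel total); a
#' larger reference (e.g. national totals) can be supplied as an explicit
#' region present in both tables, which is then excluded from the per-region
#' rows.
#'
#' @param x An `equipanel_panel` with population and area dimensions. A
#'   city-level panel is aggregated to provinces first.
#' @param categories Personnel categories to evaluate; default: all present.
#' @param reference `"panel-total"` or the name of a province in the panel
#'   to use as the reference region.
#' @return Tibble with columns `province`, `year`, `category`, `hrad`,
#'   `pad`, `ratio`, `geo_verdict`, `pop_verdict`.
#' @export
agglomeration_table <- function(x, categories = NULL,
                                reference = "panel-total") {
  validate_panel(x, basis = c("population", "area"))
  if (x$level == "city") x <- aggregate_to_province(x)
  categories <- categories %||% sort(unique(x$resources$category))
  dat <- dplyr::inner_join(x$resources, x$dimensions,
                           by = c("year", "province", "city"))
  dat <- dat[dat$category %in% categories, ]
  if (!identical(reference, "panel-total") &&
      !reference %in% dat$province) {
    stop_config(sprintf("reference region '%s' not found in the panel", reference))
  }
  out <- dat |>
    dplyr::group_by(.data$year, .data$category) |>
    dplyr::group_modify(function(sub, key) {
      if (identical(reference, "panel-total")) {
        hr_n <- sum(sub$count)
        p_n <- sum(sub$population)
        a_n <- sum(sub$area_km2)
      } else {
        ref <- sub[sub$province == reference, ]
        if (nrow(ref) != 1) {
          stop_coverage(sprintf("reference region '%s' missing for year %d, %s",
                                reference, key$year, key$category))
        }
        hr_n <- ref$count
        p_n <- ref$population
        a_n <- ref$area_km2
        sub <- sub[sub$province != reference, ]
      }
      h <- hrad(sub$count, sub$area_km2, hr_n, a_n)
      pd <- pad(sub$population, sub$area_km2, p_n, a_n)
      r <- hrad_pad_ratio(h, pd)
      v <- classify_agglomeration(h, r)
      tibble::tibble(province = sub$province, hrad = h, pad = pd, ratio = r,
                     geo_verdict = v$geo_verdict, pop_verdict = v$pop_verdict)
    }) |>
    dplyr::ungroup()
  dplyr::arrange(out[c("province", "year", "category", "hrad", "pad",
                       "ratio", "geo_verdict", "pop_verdict")],
                 .data$province, .data$year, .data$category)
}
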