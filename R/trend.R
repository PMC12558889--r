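#' Linear year-trend regression for a fairness indicator
#'
#' Ordinary least squares of an indicator on calendar year, with a t-test
#' of the slope and its 95% confidence interval — the standard way to ask
#' whether an equity index is drifting. Year enters as a raw integer
#' covariate; an origin shift (`origin`) changes only the intercept, never
#' the slope, its standard error, t or p.
#'
#' For an exactly collinear series (zero residual) the sampling theory
#' degenerates: the slope is reported with `se = 0`, a confidence interval
#' collapsed at the slope, and `p = 0` for a nonzero slope (`p = 1` for a
#' constant series, where there is no trend to detect).
#'
#' @param series Data frame with columns `year` and `value`, one row per
#'   year; at least 3 distinct years.
#' @param origin Year subtracted from the covariate before fitting
#'   (intercept reference point); default 0, i.e. raw calendar year.
#' @return A one-row tibble of class `equipanel_trend`: `slope`,
#'   `intercept`, `se`, `t`, `p`, `ci_low`, `ci_high`, `n`.
#' @examples
#' fit_trend(data.frame(year = 2014:2016, value = c(0.1, 0.2, 0.4)))
#' @export
fit_trend <- function(series, origin = 0) {
  if (!all(c("year", "value") %in% names(series))) {
    stop_schema("series needs columns 'year' and 'value'")
  }
  year <- series$year
  value <- series$value
  if (anyNA(year) || anyNA(value) || any(!is.finite(value))) {
    stop_domain("years and values must be finite")
  }
  n <- length(year)
  if (length(unique(year)) == 1 && n >= 3) {
    stop_design("year covariate is constant")
  }
  if (n < 3 || length(unique(year)) < 3) {
    stop_sample_size("at least 3 distinct years are required")
  }
  fit <- stats::lm(value ~ I(year - origin))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  rss <- sum(fit$residuals^2)
  df <- n - 2
  exact <- rss <= 1e-18 * max(sum(value^2), .Machine$double.xmin)
  if (exact) {
    zero_slope <- abs(slope) <= 1e-12 * max(1, abs(mean(value)))
    se <- 0
    t <- if (zero_slope) 0 else sign(slope) * Inf
    p <- if (zero_slope) 1 else 0
    ci <- c(slope, slope)
  } else {
    se <- sqrt(rss / df / sum((year - mean(year))^2))
    t <- slope / se
    p <- 2 * stats::pt(-abs(t), df)
    hw <- stats::qt(0.975, df) * se
    ci <- c(slope - hw, slope + hw)
  }
  out <- tibble::tibble(slope = slope, intercept = intercept, se = se,
                        t = t, p = p, ci_low = ci[1], ci_high = ci[2], n = n)
  class(out) <- c("equipanel_trend", class(out))
  out
}

#' Year-trend table of fairness indicators over a panel
#'
#' Computes an indicator series per (measure, basis, category, scope) and
#' fits [fit_trend()] to each. Supported measures: `"gini"` (within a
#' province's cities, or `"overall"` across all cities), `"theil_total"`,
#' `"theil_inter"`, `"theil_intra"` (panel-wide), `"hrad"`, `"pad"`,
#' `"hrad_pad_ratio"` (per province against the panel total).
#'
#' @param x A city-level `equipanel_panel` with the needed dimensions.
#' @param indicators Data frame with columns `measure`, `basis`,
#'   `category`, `scope` (a province name or `"overall"`); defaults to the
#'   per-province Gini on every basis x category present.
#' @param origin Passed to [fit_trend()].
#' @return Tibble with the indicator keys, an `indicator` label, and the
#'   [fit_trend()] columns, ordered by measure, basis, category, scope.
#' @export
trend_table <- function(x, indicators = NULL, origin = 0) {
  validate_panel(x)
  if (is.null(indicators)) {
    indicators <- expand.grid(measure = "gini",
                              basis = c("population", "gdp", "area"),
                              category = sort(unique(x$resources$category)),
                              scope = sort(unique(x$resources$province)),
                              stringsAsFactors = FALSE)
  }
  indicators <- tibble::as_tibble(indicators)
  indicators <- dplyr::arrange(indicators, .data$measure, .data$basis,
                               .data$category, .data$scope)
  out <- lapply(seq_len(nrow(indicators)), function(i) {
    sp <- indicators[i, ]
    series <- indicator_series(x, sp$measure, sp$basis, sp$category, sp$scope)
    fit <- fit_trend(series, origin = origin)
    dplyr::bind_cols(sp,
                     tibble::tibble(indicator = paste(sp$measure, sp$category,
                                                      sp$basis, sp$scope,
                                                      sep = ", ")),
                     tibble::as_tibble(fit))
  })
  dplyr::bind_rows(out)
}

# One (year, value) series for a named fairness measure.
indicator_series <- function(x, measure, basis, category, scope) {
  measure <- match.arg(measure, c("gini", "theil_total", "theil_inter",
                                  "theil_intra", "hrad", "pad",
                                  "hrad_pad_ratio"))
  if (measure == "gini") {
    gt <- gini_table(x, bases = basis, categories = category,
                     scope = if (identical(scope, "overall")) "overall" else "province")
    gt <- gt[gt$scope == scope, ]
    if (nrow(gt) == 0) stop_coverage(sprintf("no Gini series for scope '%s'", scope))
    tibble::tibble(year = gt$year, value = gt$gini)
  } else if (measure %in% c("theil_total", "theil_inter", "theil_intra")) {
    tt <- theil_table(x, bases = basis, categories = category)
    col <- sub("theil_", "", measure)
    tibble::tibble(year = tt$year, value = tt[[col]])
  } else {
    at <- agglomeration_table(x, categories = category)
    at <- at[at$province == scope, ]
    if (nrow(at) == 0) stop_coverage(sprintf("no agglomeration series for '%s'", scope))
    col <- c(hrad = "hrad", pad = "pad", hrad_pad_ratio = "ratio")[measure]
    tibble::tibble(year = at$year, value = at[[col]])
  }
}
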