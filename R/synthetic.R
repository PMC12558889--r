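#' Configuration for the synthetic panel generator
#'
#' Describes a province-to-prefecture staffing panel with controllable
#' inter-province and intra-province dispersion. City population and land
#' area are log-normal; GDP is population times a per-capita base with
#' log-normal noise; the per-10,000 staffing rate of province `k`, city `j`
#' in year `t` is `base_rate * exp(eta_k + eps_j + trend * (t - t0))` with
#' `eta_k ~ N(0, sigma_inter^2)` and `eps_j ~ N(0, sigma_intra^2)`.
#'
#' Defaults emulate a Yangtze-River-Delta-like setting: 4 provinces x 10
#' prefecture cities x 2014-2022, mean city population about 4 million,
#' mean area about 9,000 km2, GDP per capita 90,000 yuan, category base
#' rates near the region's 2022 per-10k staffing levels, and dispersion
#' with the within-province component dominating.
#'
#' @param n_provinces Number of provinces.
#' @param cities_per_province Cities per province; scalar or one value per
#'   province.
#' @param years Calendar years covered.
#' @param seed Integer seed fixing the full output.
#' @param pop_logmean,pop_logsd Log-normal parameters for city resident
#'   population (persons).
#' @param area_logmean,area_logsd Log-normal parameters for city land area
#'   (km2).
#' @param gdp_per_capita_base GDP per person (yuan); GDP is stored in
#'   hundred-million yuan.
#' @param gdp_noise_logsd SD of the log-normal GDP noise.
#' @param sigma_inter SD of the province-level log staffing rate.
#' @param sigma_intra SD of the city-level log staffing rate.
#' @param base_rate_per_10k Named vector of mean staffing per 10,000
#'   population per personnel category.
#' @param trend_per_year Additive annual change in the log staffing rate.
#' @param integer_counts Round headcounts to whole persons. Off by
#'   default: real-valued counts keep share identities exact.
#' @return An object of class `equipanel_synth_config`.
#' @export
synthetic_config <- function(n_provinces = 4,
                             cities_per_province = 10,
                             years = 2014:2022,
                             seed = 1L,
                             pop_logmean = log(4e6), pop_logsd = 0.5,
                             area_logmean = log(9000), area_logsd = 0.5,
                             gdp_per_capita_base = 9e4,
                             gdp_noise_logsd = 0.2,
                             sigma_inter = 0.15,
                             sigma_intra = 0.25,
                             base_rate_per_10k = c(health_technician = 70,
                                                   licensed_physician = 28,
                                                   registered_nurse = 30,
                                                   pharmacist = 3.5,
                                                   other_health_technician = 3.5),
                             trend_per_year = 0,
                             integer_counts = FALSE) {
  if (n_provinces < 1) stop_config("n_provinces must be >= 1")
  if (length(cities_per_province) == 1) {
    cities_per_province <- rep(cities_per_province, n_provinces)
  }
  if (length(cities_per_province) != n_provinces || any(cities_per_province < 1)) {
    stop_config("cities_per_province must be a positive scalar or one value per province")
  }
  if (length(years) < 1) stop_config("years must be non-empty")
  sds <- c(pop_logsd, area_logsd, gdp_noise_logsd, sigma_inter, sigma_intra)
  if (any(sds < 0)) stop_config("all standard deviations must be >= 0")
  if (is.null(names(base_rate_per_10k)) ||
      !all(names(base_rate_per_10k) %in% panel_categories()) ||
      any(base_rate_per_10k <= 0)) {
    stop_config("base_rate_per_10k must be a named, positive vector over valid categories")
  }
  structure(list(n_provinces = as.integer(n_provinces),
                 cities_per_province = as.integer(cities_per_province),
                 years = as.integer(years), seed = as.integer(seed),
                 pop_logmean = pop_logmean, pop_logsd = pop_logsd,
                 area_logmean = area_logmean, area_logsd = area_logsd,
                 gdp_per_capita_base = gdp_per_capita_base,
                 gdp_noise_logsd = gdp_noise_logsd,
                 sigma_inter = sigma_inter, sigma_intra = sigma_intra,
                 base_rate_per_10k = base_rate_per_10k,
                 trend_per_year = trend_per_year,
                 integer_counts = isTRUE(integer_counts)),
            class = "equipanel_synth_config")
}

#' Generate a synthetic province-to-prefecture panel
#'
#' Draws a complete city-level panel under a [synthetic_config()]: the same
#' seed always yields the identical panel. With both dispersion parameters
#' and the trend at zero, every city has the same per-capita staffing rate,
#' so population-basis Gini and Theil are exactly zero; with
#' `sigma_intra = 0` cities within a province share one rate, so the
#' within-province Theil component vanishes.
#'
#' @param config An `equipanel_synth_config` (default: the standard
#'   configuration).
#' @return A validated city-level [panel()].
#' @examples
#' p <- generate_panel(synthetic_config(seed = 7))
#' p
#' @export
generate_panel <- function(config = synthetic_config()) {
  if (!inherits(config, "equipanel_synth_config")) {
    stop_config("config must come from synthetic_config()")
  }
  cfg <- config
  prov <- sprintf("P%02d", seq_len(cfg$n_provinces))
  city_prov <- rep(prov, cfg$cities_per_province)
  city <- unlist(lapply(seq_len(cfg$n_provinces), function(k) {
    sprintf("%sC%02d", prov[k], seq_len(cfg$cities_per_province[k]))
  }))
  n_city <- length(city)
  withr::with_seed(cfg$seed, {
    population <- exp(rnorm(n_city, cfg$pop_logmean, cfg$pop_logsd))
    area <- exp(rnorm(n_city, cfg$area_logmean, cfg$area_logsd))
    gdp_noise <- exp(rnorm(n_city, 0, cfg$gdp_noise_logsd))
    eta <- rnorm(cfg$n_provinces, 0, cfg$sigma_inter)
    eps <- rnorm(n_city, 0, cfg$sigma_intra)
  })
  gdp <- population * cfg$gdp_per_capita_base * gdp_noise / 1e8
  city_effect <- eta[match(city_prov, prov)] + eps
  grid <- expand.grid(city_idx = seq_len(n_city), year = cfg$years,
                      category = names(cfg$base_rate_per_10k),
                      stringsAsFactors = FALSE)
  rate <- cfg$base_rate_per_10k[grid$category] *
    exp(city_effect[grid$city_idx] +
          cfg$trend_per_year * (grid$year - cfg$years[1]))
  count <- rate * population[grid$city_idx] / 1e4
  if (cfg$integer_counts) count <- round(count)
  resources <- tibble::tibble(year = as.integer(grid$year),
                              province = city_prov[grid$city_idx],
                              city = city[grid$city_idx],
                              category = grid$category,
                              count = unname(count))
  dims <- expand.grid(city_idx = seq_len(n_city), year = cfg$years,
                      stringsAsFactors = FALSE)
  dimensions <- tibble::tibble(year = as.integer(dims$year),
                               province = city_prov[dims$city_idx],
                               city = city[dims$city_idx],
                               population = population[dims$city_idx],
                               gdp = gdp[dims$city_idx],
                               area_km2 = area[dims$city_idx])
  panel(resources, dimensions, level = "city")
}

#' Impose a linear Gini path on a panel
#'
#' Rescales one category's city counts year by year so the overall grouped
#' Gini (across all cities, on the chosen basis) follows the linear path
#' `start + slope * (year - first year)` essentially exactly (within 1e-6
#' per year). The reshaping tilts city densities by a power `gamma` solved
#' per year — `gamma = 0` gives perfect equality, larger `gamma` spreads
#' densities — while preserving each year's total headcount.
#'
#' @param x A city-level `equipanel_panel` spanning at least 3 years.
#' @param slope Change in the Gini per year.
#' @param start Gini value at the first year; default: the panel's current
#'   value there.
#' @param basis Allocation basis for the target Gini.
#' @param category Personnel category whose counts are rescaled.
#' @return The panel with the category's counts replaced.
#' @export
inject_trend <- function(x, slope, start = NULL, basis = "population",
                         category = "health_technician") {
  validate_panel(x, basis = basis)
  if (x$level != "city") stop_validation("inject_trend needs a city-level panel")
  years <- sort(unique(x$resources$year))
  if (length(years) < 3) stop_sample_size("panel must span at least 3 years")
  res <- x$resources
  bcol <- basis_column(basis)
  year_data <- lapply(years, function(yr) {
    sub <- dplyr::inner_join(
      res[res$year == yr & res$category == category, ],
      x$dimensions[x$dimensions$year == yr, ],
      by = c("year", "province", "city"))
    if (nrow(sub) < 2) stop_coverage(sprintf("need >= 2 cities with '%s' in %d", category, yr))
    sub
  })
  gini_of <- function(sub, gamma) {
    b <- sub[[bcol]]
    d <- sub$count / b
    d <- d / max(d)  # d <= 1 so d^gamma never overflows
    gini_trapezoid(lorenz_points(b, b * d^gamma))
  }
  if (is.null(start)) start <- gini_of(year_data[[1]], 1)
  targets <- start + slope * (years - years[1])
  if (any(targets < 0)) stop_feasibility("target Gini path goes below 0")
  for (i in seq_along(years)) {
    sub <- year_data[[i]]
    target <- targets[i]
    g_max <- gini_of(sub, 256)
    if (target > g_max) {
      stop_feasibility(sprintf("target Gini %.4f in %d exceeds what density tilting can reach (%.4f)",
                               target, years[i], g_max))
    }
    gamma <- if (target == 0) 0 else {
      uniroot(function(g) gini_of(sub, g) - target, c(0, 256),
              tol = 1e-13)$root
    }
    if (abs(gini_of(sub, gamma) - target) > 1e-6) {
      stop_feasibility(sprintf("could not match target Gini %.4f in %d", target, years[i]))
    }
    b <- sub[[bcol]]
    d <- sub$count / b
    d <- d / max(d)
    w <- b * d^gamma
    new_count <- w * sum(sub$count) / sum(w)
    idx <- res$year == years[i] & res$category == category
    key <- paste(res$province[idx], res$city[idx])
    res$count[idx] <- new_count[match(key, paste(sub$province, sub$city))]
  }
  panel(res, x$dimensions, level = "city")
}
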