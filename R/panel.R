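#' Personnel category vocabulary
#'
#' The closed set of staffing categories a panel may contain, following the
#' Chinese health-statistics classification: the umbrella "health technician"
#' group plus its physician, nurse, pharmacist and residual sub-groups.
#'
#' @return Character vector of valid category codes.
#' @export
panel_categories <- function() {
  c("health_technician", "licensed_physician", "registered_nurse",
    "pharmacist", "other_health_technician")
}

#' Construct a regional staffing panel
#'
#' A panel couples long-format staffing headcounts (`resources`) with the
#' allocation bases (`dimensions`: resident population, GDP, land area) for
#' the same year x region keys. Counts are stored in persons. A record with
#' an empty `city` field is a province-level record.
#'
#' @param resources Data frame with columns `year`, `province`, `city`,
#'   `category`, `count` (persons).
#' @param dimensions Optional data frame with columns `year`, `province`,
#'   `city`, `population` (persons), `gdp` (hundred-million yuan),
#'   `area_km2` (square kilometres). `NULL` for panels used only for
#'   descriptive indicators that need no allocation basis.
#' @param level `"city"` or `"province"`; inferred from the `city` field
#'   when `NULL`.
#' @param validate Run [validate_panel()] on the result.
#' @return An object of class `equipanel_panel`.
#' @seealso [load_panel()], [generate_panel()]
#' @export
panel <- function(resources, dimensions = NULL, level = NULL, validate = TRUE) {
  resources <- tibble::as_tibble(resources)
  req <- c("year", "province", "city", "category", "count")
  miss <- setdiff(req, names(resources))
  if (length(miss) > 0) {
    stop_schema(paste0("resources is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  resources$city[is.na(resources$city)] <- ""
  resources <- resources[req]
  if (!is.null(dimensions)) {
    dimensions <- tibble::as_tibble(dimensions)
    reqd <- c("year", "province", "city", "population", "gdp", "area_km2")
    missd <- setdiff(reqd, names(dimensions))
    if (length(missd) > 0) {
      stop_schema(paste0("dimensions is missing column(s): ",
                         paste(missd, collapse = ", ")))
    }
    dimensions$city[is.na(dimensions$city)] <- ""
    dimensions <- dimensions[reqd]
  }
  if (is.null(level)) {
    level <- if (nrow(resources) > 0 && all(resources$city == "")) "province" else "city"
  }
  level <- match.arg(level, c("city", "province"))
  x <- structure(list(resources = resources, dimensions = dimensions,
                      level = level),
                 class = "equipanel_panel")
  if (validate) validate_panel(x) else x
}

#' @export
print.equipanel_panel <- function(x, ...) {
  cat(sprintf("<equipanel_panel> level: %s\n", x$level))
  cat(sprintf("  resources:  %d records (%d year(s), %d province(s), %d categor%s)\n",
              nrow(x$resources), length(unique(x$resources$year)),
              length(unique(x$resources$province)),
              length(unique(x$resources$category)),
              if (length(unique(x$resources$category)) == 1) "y" else "ies"))
  if (is.null(x$dimensions)) {
    cat("  dimensions: <none>\n")
  } else {
    cat(sprintf("  dimensions: %d records\n", nrow(x$dimensions)))
  }
  invisible(x)
}

#' Validate a panel against its structural invariants
#'
#' Checks the closed category vocabulary, non-negative counts, key
#' uniqueness, the city-to-province mapping, and — when a dimension table is
#' present — that every resource record has a matching dimension record.
#' Positivity of a specific allocation basis is checked only when `basis`
#' is supplied, so panels without GDP or area can still serve analyses that
#' do not need them.
#'
#' @param x An `equipanel_panel`.
#' @param basis Optional basis name(s) (`"population"`, `"gdp"`, `"area"`)
#'   whose values must be present and strictly positive.
#' @return The validated panel, invisibly usable in pipes.
#' @export
validate_panel <- function(x, basis = NULL) {
  if (!inherits(x, "equipanel_panel")) stop_validation("not an equipanel_panel")
  res <- x$resources
  if (!is.numeric(res$count)) stop_parse("resource counts are not numeric")
  if (anyNA(res$count)) stop_validation("resource counts contain missing values")
  if (any(res$count < 0)) {
    bad <- which(res$count < 0)[1]
    stop_validation(sprintf("negative count at resource row %d (%s %s %d)",
                            bad, res$province[bad], res$category[bad], res$year[bad]))
  }
  badcat <- setdiff(unique(res$category), panel_categories())
  if (length(badcat) > 0) {
    stop_validation(paste0("unknown personnel categor(ies): ",
                           paste(badcat, collapse = ", ")))
  }
  if (any(is.na(res$province) | res$province == "")) {
    stop_mapping("resource record with empty province identifier")
  }
  key <- paste(res$year, res$province, res$city, res$category, sep = "\r")
  if (anyDuplicated(key)) {
    d <- res[duplicated(key), ][1, ]
    stop_validation(sprintf("duplicate resource key: (%d, %s, %s, %s)",
                            d$year, d$province, d$city, d$category))
  }
  if (x$level == "city") {
    map <- unique(res[res$city != "", c("city", "province")])
    if (anyDuplicated(map$city)) {
      stop_mapping(sprintf("city '%s' maps to more than one province",
                           map$city[duplicated(map$city)][1]))
    }
  }
  dim <- x$dimensions
  if (!is.null(dim)) {
    for (col in c("population", "gdp", "area_km2")) {
      if (!is.numeric(dim[[col]])) stop_parse(sprintf("dimension column '%s' is not numeric", col))
    }
    dkey <- paste(dim$year, dim$province, dim$city, sep = "\r")
    if (anyDuplicated(dkey)) {
      d <- dim[duplicated(dkey), ][1, ]
      stop_validation(sprintf("duplicate dimension key: (%d, %s, %s)",
                              d$year, d$province, d$city))
    }
    rkey <- unique(paste(res$year, res$province, res$city, sep = "\r"))
    missing_cov <- setdiff(rkey, dkey)
    if (length(missing_cov) > 0) {
      shown <- gsub("\r", ", ", utils::head(missing_cov, 5))
      stop_coverage(paste0("resource records with no matching dimension record: (",
                           paste(shown, collapse = "); ("), ")"))
    }
  }
  if (!is.null(basis)) {
    if (is.null(dim)) stop_coverage("panel has no dimension table but a basis was requested")
    cols <- basis_column(basis)
    for (col in cols) {
      v <- dim[[col]]
      if (anyNA(v) || any(v <= 0)) {
        stop_validation(sprintf("dimension column '%s' must be present and > 0 for this analysis", col))
      }
    }
  }
  x
}

basis_column <- function(basis) {
  basis <- match.arg(basis, c("population", "gdp", "area"), several.ok = TRUE)
  c(population = "population", gdp = "gdp", area = "area_km2")[basis]
}

#' Aggregate a city-level panel to province level
#'
#' Sums headcounts and every additive dimension (population, GDP, land
#' area) over the member cities of each province. Aggregation is exact:
#' province totals equal the sum of city values.
#'
#' @param x A city-level `equipanel_panel`.
#' @return A province-level `equipanel_panel`.
#' @export
aggregate_to_province <- function(x) {
  validate_panel(x)
  if (x$level != "city") stop_validation("panel is already at province level")
  res <- x$resources |>
    dplyr::group_by(.data$year, .data$province, .data$category) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(city = "", .after = "province") |>
    dplyr::arrange(.data$year, .data$province, .data$category)
  dim <- x$dimensions
  if (!is.null(dim)) {
    dim <- dim |>
      dplyr::group_by(.data$year, .data$province) |>
      dplyr::summarise(population = sum(.data$population),
                       gdp = sum(.data$gdp),
                       area_km2 = sum(.data$area_km2), .groups = "drop") |>
      dplyr::mutate(city = "", .after = "province") |>
      dplyr::arrange(.data$year, .data$province)
  }
  panel(res, dim, level = "province")
}
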