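#' Load a staffing panel from CSV files
#'
#' Reads a long-format resources table (`year,province,city,category,count`)
#' and, optionally, a dimension table
#' (`year,province,city,population,gdp,area_km2`), both UTF-8 CSV with "."
#' as the decimal mark and an empty `city` field marking province-level
#' records. Region names are whitespace-trimmed. Counts given in unit
#' `"wan"` (10,000 persons, the unit of Chinese yearbook staffing tables)
#' are converted to persons on load.
#'
#' @param resource_path Path to the resources CSV.
#' @param dimension_path Path to the dimensions CSV, or `NULL` when the
#'   analysis needs no allocation basis.
#' @param count_unit Unit of the `count` column: `"persons"` (default) or
#'   `"wan"` (x 10,000).
#' @return A validated [panel()].
#' @examples
#' path <- system.file("extdata", "yrd_resources_2014_2022.csv",
#'                     package = "equipanel")
#' p <- load_panel(path, count_unit = "wan")
#' p
#' @export
load_panel <- function(resource_path, dimension_path = NULL,
                       count_unit = c("persons", "wan")) {
  count_unit <- match.arg(count_unit)
  res <- read_checked_csv(resource_path,
                          c("year", "province", "city", "category", "count"),
                          numeric_cols = c("year", "count"))
  res$province <- trimws(res$province)
  res$city <- trimws(res$city)
  res$category <- trimws(res$category)
  if (count_unit == "wan") res$count <- res$count * 1e4
  dim <- NULL
  if (!is.null(dimension_path)) {
    dim <- read_checked_csv(dimension_path,
                            c("year", "province", "city", "population",
                              "gdp", "area_km2"),
                            numeric_cols = c("year", "population", "gdp",
                                             "area_km2"))
    dim$province <- trimws(dim$province)
    dim$city <- trimws(dim$city)
  }
  panel(res, dim)
}

# Header check first (schema error naming the column), then per-cell numeric
# parse so failures carry a row number.
read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop_schema(sprintf("%s: missing column(s): %s", basename(path),
                        paste(miss, collapse = ", ")))
  }
  raw <- raw[required]
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & trimws(raw[[col]]) != "")
    if (length(bad) > 0) {
      stop_parse(sprintf("%s: non-numeric '%s' value \"%s\" at data row %d",
                         basename(path), col, raw[[col]][bad[1]], bad[1]))
    }
    raw[[col]] <- v
  }
  raw$year <- as.integer(raw$year)
  for (col in setdiff(required, numeric_cols)) {
    raw[[col]][is.na(raw[[col]])] <- ""
  }
  raw
}

#' Write a panel back to CSV
#'
#' Writes the same schemas [load_panel()] reads, with counts in persons and
#' full double precision, so a write/load round trip reproduces the panel
#' exactly.
#'
#' @param x An `equipanel_panel`.
#' @param resource_path Output path for the resources CSV.
#' @param dimension_path Output path for the dimensions CSV; required when
#'   the panel has a dimension table.
#' @return `x`, invisibly.
#' @export
write_panel <- function(x, resource_path, dimension_path = NULL) {
  validate_panel(x)
  readr::write_csv(x$resources, resource_path, progress = FALSE)
  if (!is.null(x$dimensions)) {
    if (is.null(dimension_path)) {
      stop_config("panel has a dimension table; supply dimension_path")
    }
    readr::write_csv(x$dimensions, dimension_path, progress = FALSE)
  }
  invisible(x)
}

#' Yangtze River Delta province-level staffing panel, 2014-2022
#'
#' The published province-level headcounts for the four Yangtze River Delta
#' provinces (Jiangsu, Zhejiang, Shanghai, Anhui) over 2014-2022, five
#' personnel categories, shipped with the package as a CSV in the yearbook
#' unit of 10,000 persons and converted to persons on load. This panel has
#' no dimension table, so it supports the descriptive indicators (growth
#' rates, healthcare ratios) but not basis-dependent indices.
#'
#' @return A province-level [panel()].
#' @examples
#' p <- yrd_panel()
#' growth_rate(p, "registered_nurse", 2014, 2022)
#' @export
yrd_panel <- function() {
  path <- system.file("extdata", "yrd_resources_2014_2022.csv",
                      package = "equipanel", mustWork = TRUE)
  load_panel(path, count_unit = "wan")
}
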