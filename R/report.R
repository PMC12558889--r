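#' Configure a full equity analysis run
#'
#' @param resource_path,dimension_path CSV inputs for [load_panel()];
#'   alternatively pass a ready-made panel to [run_analysis()] directly.
#' @param count_unit Unit of the resource counts (`"persons"` or `"wan"`).
#' @param bases Allocation bases to evaluate; at least one.
#' @param categories Personnel categories; `"all"` or a subset of
#'   [panel_categories()]; at least one.
#' @param level Analysis level of the input panel (`"city"` or
#'   `"province"`).
#' @param group_by Grouping key for the Theil decomposition.
#' @param reference Agglomeration reference: `"panel-total"` or a region
#'   name.
#' @param out_dir Output directory for the result tables.
#' @param rounding Apply the report rounding profile at serialization
#'   (indices to 3 decimals, contribution and growth percentages to 2);
#'   in-memory results always keep full precision.
#' @return An object of class `equipanel_analysis_config`.
#' @export
analysis_config <- function(resource_path = NULL, dimension_path = NULL,
                            count_unit = "persons",
                            bases = c("population", "gdp", "area"),
                            categories = "all",
                            level = c("city", "province"),
                            group_by = "province",
                            reference = "panel-total",
                            out_dir = NULL,
                            rounding = TRUE) {
  bases <- match.arg(bases, c("population", "gdp", "area"), several.ok = TRUE)
  if (identical(categories, "all")) categories <- panel_categories()
  bad <- setdiff(categories, panel_categories())
  if (length(categories) == 0 || length(bad) > 0) {
    stop_config("categories must be a non-empty subset of panel_categories()")
  }
  if (length(bases) == 0) stop_config("select at least one basis")
  structure(list(resource_path = resource_path,
                 dimension_path = dimension_path,
                 count_unit = count_unit, bases = bases,
                 categories = categories, level = match.arg(level),
                 group_by = group_by, reference = reference,
                 out_dir = out_dir, rounding = isTRUE(rounding)),
            class = "equipanel_analysis_config")
}

#' Run the full equity analysis
#'
#' Ties the pipeline together: loads (or takes) a panel, then per basis x
#' category emits the per-province Gini table, the panel-wide Theil
#' decomposition with contribution rates, per-province HRAD/PAD/ratio
#' tables, the descriptive staffing table with aggregate growth rates, and
#' a year-trend regression table. Stages whose allocation basis is absent
#' from the panel (e.g. a province-level table with no dimension data) are
#' skipped and noted in the run log. Identical config and inputs give
#' byte-identical outputs.
#'
#' @param config An `equipanel_analysis_config`.
#' @param panel_obj Optional pre-built `equipanel_panel`, used instead of
#'   reading `config$resource_path`.
#' @return Invisibly, a named list of result tibbles (`descriptives`,
#'   `growth`, and, where computable, `gini`, `theil`, `agglomeration`,
#'   `trends`), also written as CSVs plus a JSON bundle and run log when
#'   `config$out_dir` is set.
#' @export
run_analysis <- function(config, panel_obj = NULL) {
  if (!inherits(config, "equipanel_analysis_config")) {
    stop_config("config must come from analysis_config()")
  }
  pn <- panel_obj %||% load_panel(config$resource_path, config$dimension_path,
                                  count_unit = config$count_unit)
  validate_panel(pn)
  log_lines <- c("equipanel run log",
                 paste0("package version: ",
                        as.character(utils::packageVersion("equipanel"))),
                 paste0("level: ", pn$level),
                 paste0("bases: ", paste(config$bases, collapse = ",")),
                 paste0("categories: ", paste(config$categories, collapse = ",")),
                 paste0("reference: ", config$reference))
  cats <- intersect(config$categories, unique(pn$resources$category))
  has_dims <- !is.null(pn$dimensions)
  usable_basis <- function(b) {
    has_dims && {
      v <- pn$dimensions[[basis_column(b)]]
      !anyNA(v) && all(v > 0)
    }
  }
  bases <- Filter(usable_basis, config$bases)
  skipped <- setdiff(config$bases, bases)
  if (length(skipped) > 0) {
    log_lines <- c(log_lines,
                   paste0("skipped bases (dimension data absent): ",
                          paste(skipped, collapse = ",")))
  }

  results <- list()
  with_stage <- function(stage, expr) {
    tryCatch(expr, equipanel_error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                   class = class(e), parent = e)
    })
  }
  results$descriptives <- with_stage("descriptives", descriptive_table(pn))
  years <- sort(unique(pn$resources$year))
  if (length(years) >= 2) {
    y0 <- years[1]; y1 <- years[length(years)]
    results$growth <- with_stage("growth", tibble::tibble(
      category = cats, year0 = y0, year1 = y1,
      growth_pct = vapply(cats, function(ct) growth_rate(pn, ct, y0, y1),
                          numeric(1), USE.NAMES = FALSE)))
  }
  if (pn$level == "city" && length(bases) > 0) {
    results$gini <- with_stage("gini",
      gini_table(pn, bases = bases, categories = cats))
    results$theil <- with_stage("theil",
      theil_table(pn, bases = bases, categories = cats,
                  group_by = config$group_by))
    if (all(c("population", "area") %in% bases)) {
      results$agglomeration <- with_stage("agglomeration",
        agglomeration_table(pn, categories = cats,
                            reference = config$reference))
    }
    if (length(years) >= 3) {
      ind <- expand.grid(measure = "gini", basis = bases, category = cats,
                         scope = sort(unique(pn$resources$province)),
                         stringsAsFactors = FALSE)
      results$trends <- with_stage("trends", trend_table(pn, ind))
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    serial <- results
    if (config$rounding) serial <- round_results(serial)
    for (nm in names(serial)) {
      readr::write_csv(serial[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
    jsonlite::write_json(serial, file.path(config$out_dir, "bundle.json"),
                         dataframe = "rows", digits = NA, na = "null")
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(results)
}

# Report rounding profile: indices to 3 decimals, percentage-like and ratio
# columns to 2; keys untouched.
round_results <- function(results) {
  three <- c("gini", "total", "inter", "intra", "slope", "intercept",
             "se", "t", "ci_low", "ci_high", "hrad", "pad", "ratio")
  two <- c("contrib_inter", "contrib_intra", "growth_pct")
  lapply(results, function(tb) {
    for (col in intersect(names(tb), three)) tb[[col]] <- round_half_up(tb[[col]], 3)
    for (col in intersect(names(tb), two)) tb[[col]] <- round_half_up(tb[[col]], 2)
    tb
  })
}
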