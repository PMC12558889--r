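#' Theil index of grouped shares
#'
#' `T = sum F_i * ln(F_i / P_i)` over regions, where `F_i` is the region's
#' share of the health resource and `P_i` its share of the allocation basis
#' (population, GDP or area). Natural logarithm throughout; terms with
#' `F_i = 0` contribute 0 by continuity. Non-negative by Jensen's
#' inequality, 0 iff `F = P`.
#'
#' @param f Resource shares, summing to 1 (tolerance 1e-9).
#' @param p Basis shares, summing to 1; `p > 0` wherever `f > 0`.
#' @return The Theil index, a non-negative scalar.
#' @examples
#' theil_index(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))
#' @export
theil_index <- function(f, p) {
  if (length(f) != length(p) || length(f) == 0) {
    stop_domain("f and p must be non-empty and of equal length")
  }
  if (any(f < 0) || any(p < 0)) stop_domain("shares must be >= 0")
  if (any(f > 0 & p == 0)) {
    stop_domain("a region with positive resource share has zero basis share")
  }
  if (abs(sum(f) - 1) > 1e-9 || abs(sum(p) - 1) > 1e-9) {
    stop_normalization("resource and basis shares must each sum to 1")
  }
  pos <- f > 0
  sum(f[pos] * log(f[pos] / p[pos]))
}

#' Theil decomposition into between- and within-group components
#'
#' Splits the Theil index of city-level shares into a between-province
#' component `T_inter = sum_k F_k ln(F_k / P_k)` and a within-province
#' component `T_intra = sum_k F_k T_k`, where `F_k`, `P_k` are province
#' totals and `T_k` is the Theil index of the group-renormalised city
#' shares (`F_i / F_k` vs `P_i / P_k`) — the convention under which
#' `T = T_inter + T_intra` holds exactly. Contribution rates are each
#' component over the total, as percentages; both are `NA` when the total
#' is 0 (perfect equality).
#'
#' @param group Group (province) identifier per city.
#' @param f City resource shares (global, summing to 1).
#' @param p City basis shares (global, summing to 1).
#' @return An object of class `equipanel_theil`: fields `total`, `inter`,
#'   `intra`, `per_group` (tibble: `group`, `theil`, `f_share`, `p_share`),
#'   `contrib_inter`, `contrib_intra`.
#' @examples
#' theil_decompose(c("A", "A", "B", "B"),
#'                 c(0.3, 0.3, 0.2, 0.2), c(0.2, 0.2, 0.3, 0.3))
#' @export
theil_decompose <- function(group, f, p) {
  if (length(group) != length(f) || length(f) != length(p)) {
    stop_domain("group, f and p must have equal length")
  }
  if (anyNA(group)) stop_mapping("every city must be assigned to a group")
  total <- theil_index(f, p)
  groups <- unique(as.character(group))
  fk <- vapply(groups, function(g) sum(f[group == g]), numeric(1))
  pk <- vapply(groups, function(g) sum(p[group == g]), numeric(1))
  if (any(fk > 0 & pk == 0)) {
    stop_domain("a group with positive resource share has zero basis share")
  }
  pos <- fk > 0
  inter <- sum(fk[pos] * log(fk[pos] / pk[pos]))
  tk <- vapply(seq_along(groups), function(i) {
    if (fk[i] <= 0) return(0)
    idx <- group == groups[i]
    fi <- f[idx] / fk[i]
    pi <- p[idx] / pk[i]
    posi <- fi > 0
    sum(fi[posi] * log(fi[posi] / pi[posi]))
  }, numeric(1))
  intra <- sum(fk * tk)
  contrib <- if (total > 0) c(inter, intra) / total * 100 else c(NA_real_, NA_real_)
  structure(list(total = total, inter = inter, intra = intra,
                 per_group = tibble::tibble(group = groups, theil = tk,
                                            f_share = fk, p_share = pk),
                 contrib_inter = contrib[1], contrib_intra = contrib[2]),
            class = "equipanel_theil")
}

#' @export
print.equipanel_theil <- function(x, ...) {
  cat(sprintf("<equipanel_theil> total %.6f = inter %.6f + intra %.6f\n",
              x$total, x$inter, x$intra))
  if (is.na(x$contrib_inter)) {
    cat("  contributions: undefined (total is 0)\n")
  } else {
    cat(sprintf("  contributions: inter %.2f%%, intra %.2f%%\n",
                x$contrib_inter, x$contrib_intra))
  }
  invisible(x)
}

#' Contribution rates of a Theil decomposition
#'
#' @param x An `equipanel_theil` result.
#' @return Named numeric vector `c(inter = , intra = )` in percent, summing
#'   to 100; both `NA` when the total index is 0.
#' @export
contribution_rates <- function(x) {
  if (!inherits(x, "equipanel_theil")) stop_domain("not an equipanel_theil result")
  c(inter = x$contrib_inter, intra = x$contrib_intra)
}

#' Theil decomposition table from a city-level panel
#'
#' For each year, basis and category, computes the Theil index across all
#' prefecture-level cities and decomposes it by province.
#'
#' @inheritParams gini_table
#' @param group_by Grouping key for the decomposition (column of the
#'   resource table; default `"province"`).
#' @return Tibble with columns `year`, `basis`, `category`, `total`,
#'   `inter`, `intra`, `contrib_inter`, `contrib_intra`.
#' @export
theil_table <- function(x, bases = c("population", "gdp", "area"),
                        categories = NULL, group_by = "province") {
  bases <- match.arg(bases, c("population", "gdp", "area"), several.ok = TRUE)
  validate_panel(x, basis = bases)
  if (x$level != "city") stop_validation("theil_table needs a city-level panel")
  categories <- categories %||% sort(unique(x$resources$category))
  dat <- dplyr::inner_join(x$resources, x$dimensions,
                           by = c("year", "province", "city"))
  dat <- dat[dat$category %in% categories, ]
  grid <- expand.grid(year = sort(unique(dat$year)), basis = bases,
                      category = sort(unique(dat$category)),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- dat[dat$year == g$year & dat$category == g$category, ]
    b <- sub[[basis_column(g$basis)]]
    dec <- theil_decompose(sub[[group_by]], sub$count / sum(sub$count),
                           b / sum(b))
    tibble::tibble(year = g$year, basis = g$basis, category = g$category,
                   total = dec$total, inter = dec$inter, intra = dec$intra,
                   contrib_inter = dec$contrib_inter,
                   contrib_intra = dec$contrib_intra)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$year, .data$basis, .data$category)
}
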