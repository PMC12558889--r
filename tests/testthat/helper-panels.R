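# Small panels built in code for the unit tests.

tiny_resources <- function() {
  tibble::tibble(
    year = rep(c(2020L, 2021L), each = 4),
    province = rep(rep(c("A", "B"), each = 2), 2),
    city = rep(c("A1", "A2", "B1", "B2"), 2),
    category = "health_technician",
    count = c(100, 200, 300, 400, 110, 210, 330, 440))
}

tiny_dimensions <- function() {
  tibble::tibble(
    year = rep(c(2020L, 2021L), each = 4),
    province = rep(rep(c("A", "B"), each = 2), 2),
    city = rep(c("A1", "A2", "B1", "B2"), 2),
    population = rep(c(1e5, 2e5, 3e5, 4e5), 2),
    gdp = rep(c(10, 20, 30, 40), 2),
    area_km2 = rep(c(1000, 2000, 1500, 2500), 2))
}

tiny_panel <- function() panel(tiny_resources(), tiny_dimensions())

# Random grouped shares for property tests: n regions, m groups.
random_grouped <- function(n, m = NULL) {
  basis <- runif(n, 0.1, 5)
  resource <- runif(n, 0, 5)
  if (sum(resource) == 0) resource[1] <- 1
  group <- if (is.null(m)) NULL else sample(paste0("G", seq_len(m)), n, replace = TRUE)
  list(basis = basis, resource = resource, group = group)
}

write_tiny_csvs <- function(dir, resources = tiny_resources(),
                            dimensions = tiny_dimensions()) {
  rp <- file.path(dir, "resources.csv")
  dp <- file.path(dir, "dimensions.csv")
  readr::write_csv(resources, rp, progress = FALSE)
  readr::write_csv(dimensions, dp, progress = FALSE)
  list(resources = rp, dimensions = dp)
}
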