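test_that("write/load round trip reproduces a panel to full precision", {
  dir <- withr::local_tempdir()
  p <- tiny_panel()
  # perturbed counts exercise full double precision through the CSV layer
  p$resources$count <- p$resources$count * (1 + pi * 1e-7)
  write_panel(p, file.path(dir, "r.csv"), file.path(dir, "d.csv"))
  p2 <- load_panel(file.path(dir, "r.csv"), file.path(dir, "d.csv"))
  expect_identical(p2$resources$count, p$resources$count)
  expect_identical(p2$dimensions$population, p$dimensions$population)
  expect_identical(p2$level, "city")
})

test_that("counts in 'wan' are converted exactly to persons", {
  dir <- withr::local_tempdir()
  res <- tibble::tibble(year = 2014L, province = "Jiangsu", city = "",
                        category = "health_technician", count = 45.85)
  readr::write_csv(res, file.path(dir, "r.csv"), progress = FALSE)
  p <- load_panel(file.path(dir, "r.csv"), count_unit = "wan")
  expect_equal(p$resources$count, 458500)
  expect_identical(p$level, "province")
})

test_that("schema and parse failures are reported with column and row", {
  dir <- withr::local_tempdir()
  res <- tiny_resources()
  readr::write_csv(res[setdiff(names(res), "category")],
                   file.path(dir, "r.csv"), progress = FALSE)
  expect_error(load_panel(file.path(dir, "r.csv")),
               class = "equipanel_schema_error")
  expect_error(load_panel(file.path(dir, "r.csv")), "category")

  res$count <- as.character(res$count)
  res$count[3] <- "lots"
  readr::write_csv(res, file.path(dir, "r2.csv"), progress = FALSE)
  err <- expect_error(load_panel(file.path(dir, "r2.csv")),
                      class = "equipanel_parse_error")
  expect_match(conditionMessage(err), "row 3")
})

test_that("validation rejects invariant violations", {
  res <- tiny_resources()
  res$count[1] <- -1
  expect_error(panel(res, tiny_dimensions()),
               class = "equipanel_validation_error")

  res <- tiny_resources()
  res2 <- rbind(res, res[1, ])
  expect_error(panel(res2, tiny_dimensions()),
               class = "equipanel_validation_error")

  res <- tiny_resources()
  res$category[1] <- "astronaut"
  expect_error(panel(res, tiny_dimensions()),
               class = "equipanel_validation_error")

  dims <- tiny_dimensions()
  dims <- dims[dims$city != "A2", ]
  err <- expect_error(panel(tiny_resources(), dims),
                      class = "equipanel_coverage_error")
  expect_match(conditionMessage(err), "A2")

  # same city claimed by two provinces
  res <- tiny_resources()
  res$city[res$city == "B1"] <- "A1"
  expect_error(panel(res, tiny_dimensions(), level = "city", validate = TRUE),
               class = "equipanel_mapping_error")

  expect_identical(validate_panel(tiny_panel()), tiny_panel())
})

test_that("basis-aware validation tolerates missing bases until requested", {
  dims <- tiny_dimensions()
  dims$gdp <- NA_real_
  p <- panel(tiny_resources(), dims)
  expect_s3_class(validate_panel(p, basis = "population"), "equipanel_panel")
  expect_error(validate_panel(p, basis = "gdp"),
               class = "equipanel_validation_error")
})

test_that("province aggregation conserves every additive quantity", {
  p <- tiny_panel()
  agg <- aggregate_to_province(p)
  expect_identical(agg$level, "province")
  expect_equal(nrow(agg$resources), 4)  # 2 provinces x 2 years x 1 category
  a2020 <- agg$resources[agg$resources$year == 2020, ]
  expect_equal(a2020$count[a2020$province == "A"], 300)
  expect_equal(a2020$count[a2020$province == "B"], 700)
  expect_equal(sum(agg$resources$count), sum(p$resources$count))
  for (col in c("population", "gdp", "area_km2")) {
    expect_equal(sum(agg$dimensions[[col]]), sum(p$dimensions[[col]]))
  }
  expect_error(aggregate_to_province(agg),
               class = "equipanel_validation_error")
})

test_that("aggregation conserves sums on randomized panels", {
  set.seed(42)
  for (rep in 1:10) {
    cfg <- synthetic_config(n_provinces = sample(2:5, 1),
                            cities_per_province = sample(2:6, 1),
                            years = 2019:2021, seed = rep)
    p <- generate_panel(cfg)
    agg <- aggregate_to_province(p)
    expect_equal(sum(agg$resources$count), sum(p$resources$count))
    expect_equal(sum(agg$dimensions$population), sum(p$dimensions$population))
  }
})
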