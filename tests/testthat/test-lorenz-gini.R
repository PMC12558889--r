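test_that("Lorenz vertices rank regions by density and accumulate shares", {
  expect_equal(lorenz_points(1, 5),
               tibble::tibble(x = c(0, 1), y = c(0, 1)))

  lz <- lorenz_points(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
  expect_equal(lz$x, c(0, 0.5, 0.8, 1))
  expect_equal(lz$y, c(0, 0.2, 0.5, 1))

  # equal densities put every vertex on the diagonal
  lz_eq <- lorenz_points(c(2, 5, 3), c(2, 5, 3) * 7)
  expect_equal(lz_eq$x, lz_eq$y)

  expect_error(lorenz_points(c(1, 0), c(1, 1)), class = "equipanel_domain_error")
  expect_error(lorenz_points(numeric(0), numeric(0)),
               class = "equipanel_domain_error")
})

test_that("trapezoid Gini matches hand-derived values and edge cases", {
  # perfect equality: exactly zero, not merely close
  lz_eq <- lorenz_points(c(2, 5, 3), c(2, 5, 3))
  expect_identical(gini_trapezoid(lz_eq), 0)

  # two equal-basis regions, all resource in one
  lz <- lorenz_points(c(1, 1), c(0, 1))
  expect_equal(gini_trapezoid(lz), 0.5)

  expect_equal(gini_trapezoid(lorenz_points(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))),
               0.39)

  bad <- tibble::tibble(x = c(0, 0.8, 0.5, 1), y = c(0, 0.1, 0.3, 1))
  expect_error(gini_trapezoid(bad), class = "equipanel_domain_error")
})

test_that("pairwise-difference Gini reproduces hand-computed values", {
  expect_equal(gini_pairwise(c(0.3, 0.7), c(2, 2)), 0)
  expect_equal(gini_pairwise(c(0.5, 0.3, 0.2), c(0.4, 1.0, 2.5)), 0.39)
  expect_equal(gini_pairwise(c(0.5, 0.5), c(0, 2)), 0.5)
  expect_error(gini_pairwise(c(0.6, 0.6), c(1, 2)),
               class = "equipanel_normalization_error")
  expect_error(gini_pairwise(c(0.5, 0.5), c(0, 0)),
               class = "equipanel_domain_error")
})

test_that("trapezoid and pairwise routes agree to 1e-12 on random grouped data", {
  set.seed(101)
  worst <- 0
  for (i in 1:400) {
    g <- random_grouped(sample(1:20, 1))
    g1 <- gini_trapezoid(lorenz_points(g$basis, g$resource))
    g2 <- gini_pairwise(g$basis / sum(g$basis), g$resource / g$basis)
    worst <- max(worst, abs(g1 - g2))
  }
  expect_lt(worst, 1e-12)
})

test_that("Gini is scale invariant and merge consistent, with the grouped bound", {
  set.seed(202)
  for (i in 1:50) {
    g <- random_grouped(sample(2:15, 1))
    base <- gini_trapezoid(lorenz_points(g$basis, g$resource))
    expect_equal(gini_trapezoid(lorenz_points(g$basis, g$resource * 137)), base)
    expect_equal(gini_trapezoid(lorenz_points(g$basis * 0.013, g$resource)), base)

    # split region 1 into two pieces with identical density
    basis2 <- c(g$basis[1] * c(0.3, 0.7), g$basis[-1])
    res2 <- c(g$resource[1] * c(0.3, 0.7), g$resource[-1])
    expect_equal(gini_trapezoid(lorenz_points(basis2, res2)), base,
                 tolerance = 1e-12)

    expect_gte(base, 0)
    expect_lte(base, 1 - min(g$basis) / sum(g$basis) + 1e-12)
  }
})

test_that("fairness bands are half-open with 0.4 on the unfair side", {
  expect_identical(classify_gini(0.142), "high")
  expect_identical(classify_gini(0), "high")
  expect_identical(
    classify_gini(c(0.199999, 0.2, 0.299999, 0.3, 0.399999, 0.4, 1)),
    c("high", "comparative", "comparative", "relative", "relative",
      "unfair", "unfair"))
  expect_error(classify_gini(1.2), class = "equipanel_domain_error")
  expect_error(classify_gini(-0.1), class = "equipanel_domain_error")
})

test_that("gini_index bundles value, classification and polygon", {
  gi <- gini_index(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5), basis_name = "gdp",
                   category = "registered_nurse")
  expect_s3_class(gi, "equipanel_gini")
  expect_equal(gi$value, 0.39)
  expect_identical(gi$classification, "relative")
  expect_equal(nrow(gi$lorenz), 4)
  expect_output(print(gi), "0.39")
})

test_that("gini_table computes per-province and pooled tables deterministically", {
  p <- generate_panel(synthetic_config(seed = 11, n_provinces = 3,
                                       cities_per_province = 4,
                                       years = 2019:2021))
  gt <- gini_table(p, bases = c("population", "gdp"))
  expect_equal(nrow(gt), 3 * 3 * 2 * 5)  # provinces x years x bases x categories
  expect_true(all(gt$gini >= 0 & gt$gini < 1))
  expect_identical(gt, gini_table(p, bases = c("population", "gdp")))

  ov <- gini_table(p, bases = "population", categories = "registered_nurse",
                   scope = "overall")
  expect_equal(unique(ov$scope), "overall")
  expect_equal(nrow(ov), 3)
})
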