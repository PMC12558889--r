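test_that("the same seed yields an identical panel, different seeds differ", {
  a <- generate_panel(synthetic_config(seed = 99))
  b <- generate_panel(synthetic_config(seed = 99))
  expect_identical(a, b)
  c <- generate_panel(synthetic_config(seed = 100))
  expect_false(identical(a$resources$count, c$resources$count))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(generate_panel(synthetic_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("generated panels pass validation for every shape tried", {
  set.seed(606)
  for (i in 1:8) {
    cfg <- synthetic_config(n_provinces = sample(2:5, 1),
                            cities_per_province = sample(2:8, 1),
                            years = 2014:(2014 + sample(2:8, 1)), seed = i)
    p <- generate_panel(cfg)
    expect_s3_class(validate_panel(p, basis = c("population", "gdp", "area")),
                    "equipanel_panel")
    expect_identical(p$level, "city")
  }
})

test_that("zero dispersion gives exactly equal per-capita rates", {
  p <- generate_panel(synthetic_config(seed = 3, sigma_inter = 0,
                                       sigma_intra = 0, trend_per_year = 0))
  gt <- gini_table(p, bases = "population")
  expect_true(all(gt$gini < 1e-12))
  tt <- theil_table(p, bases = "population")
  expect_true(all(tt$total < 1e-12))
})

test_that("zero within-province dispersion kills the intra component and vice versa", {
  p_intra0 <- generate_panel(synthetic_config(seed = 17, sigma_intra = 0))
  tt <- theil_table(p_intra0, bases = "population",
                    categories = "health_technician")
  expect_true(all(tt$intra < 1e-9))
  expect_true(all(tt$inter > 1e-6))  # dispersion moved between provinces

  p_inter0 <- generate_panel(synthetic_config(seed = 17, sigma_inter = 0))
  tt2 <- theil_table(p_inter0, bases = "population",
                     categories = "health_technician")
  expect_true(all(tt2$intra > 1e-6))
})

test_that("raising sigma_inter does not lower the between component on average", {
  lo <- hi <- numeric(200)
  for (i in seq_len(200)) {
    p_lo <- generate_panel(synthetic_config(seed = 7000 + i, sigma_inter = 0.05,
                                            years = 2020L))
    p_hi <- generate_panel(synthetic_config(seed = 7000 + i, sigma_inter = 0.35,
                                            years = 2020L))
    get_inter <- function(p) {
      theil_table(p, bases = "population",
                  categories = "health_technician")$inter
    }
    lo[i] <- get_inter(p_lo)
    hi[i] <- get_inter(p_hi)
  }
  expect_gt(mean(hi), mean(lo))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_provinces = 0), class = "equipanel_config_error")
  expect_error(synthetic_config(sigma_intra = -1), class = "equipanel_config_error")
  expect_error(synthetic_config(base_rate_per_10k = c(wizard = 5)),
               class = "equipanel_config_error")
  expect_error(generate_panel(list(seed = 1)), class = "equipanel_config_error")
})

test_that("an injected Gini path is followed linearly and recovered by OLS", {
  p <- generate_panel(synthetic_config(seed = 55))
  p2 <- inject_trend(p, slope = -0.01, start = 0.30)
  g <- gini_table(p2, bases = "population", categories = "health_technician",
                  scope = "overall")
  expect_equal(g$gini, 0.30 - 0.01 * (g$year - 2014), tolerance = 1e-6)
  fit <- fit_trend(data.frame(year = g$year, value = g$gini))
  expect_equal(fit$slope, -0.01, tolerance = 1e-6)

  # zero slope leaves the indicator flat at its current level
  flat <- inject_trend(p, slope = 0)
  gf <- gini_table(flat, bases = "population", categories = "health_technician",
                   scope = "overall")
  expect_lt(diff(range(gf$gini)), 1e-9)

  expect_error(inject_trend(p, slope = -0.05, start = 0.1),
               class = "equipanel_feasibility_error")
  expect_error(inject_trend(p, slope = 0.2, start = 0.9),
               class = "equipanel_feasibility_error")
})

test_that("other categories and totals are untouched by injection", {
  p <- generate_panel(synthetic_config(seed = 56))
  p2 <- inject_trend(p, slope = -0.005, start = 0.25,
                     category = "registered_nurse")
  keep <- p$resources$category != "registered_nurse"
  expect_identical(p2$resources$count[keep], p$resources$count[keep])
  for (yr in 2014:2022) {
    sel <- p$resources$year == yr & !keep
    expect_equal(sum(p2$resources$count[sel]), sum(p$resources$count[sel]))
  }
})
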