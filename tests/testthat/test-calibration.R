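test_that("proportional fit is exact least squares through the origin", {
  m <- fit_proportional(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m$coefficients[["slope"]], 2)
  expect_equal(m$r, 1)

  # hand arithmetic: sum(xy) = 28.5, sum(x^2) = 14
  m <- fit_proportional(c(1, 2, 3), c(2.1, 3.9, 6.2))
  expect_equal(m$coefficients[["slope"]], 28.5 / 14)

  m <- fit_proportional(c(1, 2, 3), c(5, 5, 5))
  expect_equal(m$coefficients[["slope"]], sum(c(5, 10, 15)) / 14)
  expect_true(is.na(m$r)) # zero response variance: correlation undefined

  expect_error(fit_proportional(c(0, 0), c(1, 2)),
               class = "rededge_degenerate_predictor_error")
  expect_error(fit_proportional(1, 2), class = "rededge_usage_error")
})

test_that("proportional fit recovers a seeded noisy slope within 3 standard errors", {
  # property across 100 replicates: through-origin slope estimator with
  # se = sigma / sqrt(sum(x^2)); allow the expected normal-tail exceptions
  set.seed(20)
  hits <- 0L
  for (i in 1:100) {
    x <- runif(200, 0.05, 0.7)
    sigma <- 0.8
    y <- 6.753 * x + rnorm(200, 0, sigma)
    m <- fit_proportional(x, y)
    se <- sigma / sqrt(sum(x^2))
    if (abs(m$coefficients[["slope"]] - 6.753) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 96)
})

test_that("linear fit recovers exact lines and behaves like OLS under noise", {
  x <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  m <- fit_linear(x, -3.8868 + 101.94 * x)
  expect_equal(m$coefficients[["intercept"]], -3.8868, tolerance = 1e-10)
  expect_equal(m$coefficients[["slope"]], 101.94, tolerance = 1e-10)
  expect_equal(m$r, 1)

  m <- fit_linear(c(0, 1), c(1, 3))
  expect_equal(unname(m$coefficients), c(1, 2))

  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)),
               class = "rededge_degenerate_predictor_error")

  set.seed(7)
  n <- 1000
  x <- runif(n, 0, 0.6)
  sigma <- 4
  y <- -3.8868 + 101.94 * x + rnorm(n, 0, sigma)
  m <- fit_linear(x, y)
  se_slope <- sigma / sqrt(sum((x - mean(x))^2))
  se_int <- sigma * sqrt(1 / n + mean(x)^2 / sum((x - mean(x))^2))
  expect_lt(abs(m$coefficients[["slope"]] - 101.94), 3 * se_slope)
  expect_lt(abs(m$coefficients[["intercept"]] + 3.8868), 3 * se_int)
})

test_that("exponential fit is the identity on noiseless data and rejects bad input", {
  x <- seq(0.1, 0.6, by = 0.1)
  m <- fit_exponential(x, 0.0219 * exp(10.02 * x))
  expect_equal(m$coefficients[["A"]], 0.0219, tolerance = 1e-12)
  expect_equal(m$coefficients[["k"]], 10.02, tolerance = 1e-12)
  expect_equal(m$r, 1)

  expect_error(fit_exponential(c(0.1, 0.2), c(1, 2)),
               class = "rededge_usage_error") # n >= 3
  expect_error(fit_exponential(c(0.1, 0.2, 0.3), c(1, -2, 3)),
               regexp = "indices", class = "rededge_domain_error")
})

test_that("exponential fit recovers parameters within 5% under lognormal noise", {
  set.seed(11)
  n <- 500
  x <- runif(n, 0.1, 0.6)
  y <- 0.0219 * exp(10.02 * x) * exp(rnorm(n, 0, 0.2))
  m <- fit_exponential(x, y)
  expect_lt(abs(m$coefficients[["A"]] - 0.0219) / 0.0219, 0.05)
  expect_lt(abs(m$coefficients[["k"]] - 10.02) / 10.02, 0.05)
})

test_that("calibration presets apply their printed functional forms", {
  expect_equal(predict(calibration_preset("ndi_lai_s2"), 0.5), 4.226)
  expect_equal(predict(calibration_preset("naoc_chlai"), 0), 0.0219)
  expect_equal(predict(calibration_preset("naoc_ch"), 0), -3.8868)
  expect_equal(predict(calibration_preset("ndi_lai_hyperspectral"), 1), 6.753)
})

test_that("predict on maps propagates masks and records provenance", {
  cube <- matrix_cube(c(674, 712), rbind(c(0.1, 0.3), c(NA, NA)))
  map <- ndi(cube, 674, 712)
  out <- predict(calibration_preset("ndi_lai_s2"), map)
  expect_equal(out$value[1], 8.452 * 0.5)
  expect_true(is.na(out$value[2]))
  expect_equal(map_meta(out)$calibration$kind, "proportional")

  all_masked <- dplyr::mutate(map, value = NA_real_)
  out <- predict(calibration_preset("ndi_lai_s2"), all_masked)
  expect_true(all(is.na(out$value)))
})

test_that("predict-then-fit r equals the stored fit r for affine model forms", {
  set.seed(31)
  x <- runif(50, 0.1, 0.8)
  y <- 5 * x + rnorm(50, 0, 0.3)
  m <- fit_proportional(x, y)
  expect_equal(cor(predict(m, x), y), m$r)
})

test_that("calibration models serialize to JSON and back", {
  m <- fit_exponential(c(0.1, 0.3, 0.5), c(0.05, 0.4, 3.2))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_calibration(m, path)
  back <- read_calibration(path)
  expect_equal(back$kind, "exponential")
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$r, m$r)
})

test_that("tidy and glance summarize calibration models", {
  m <- fit_linear(c(0, 1, 2), c(1, 3, 5))
  expect_equal(tidy(m)$term, c("intercept", "slope"))
  g <- glance(m)
  expect_equal(g$kind, "linear")
  expect_equal(g$n, 3L)
})

test_that("validation reports reproduce hand-computed statistics", {
  map <- new_map_for_test(values = c(1, 2, 3, 4))
  truth <- tibble::tibble(pixel_row = 0:3, pixel_col = 0L,
                          value = c(1, 2, 3, 4))
  rep <- validate_map(map, truth)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$bias, 0)
  expect_equal(rep$n, 4)

  truth2 <- tibble::tibble(pixel_row = 0:1, pixel_col = 0L,
                           value = c(0, 3))
  rep <- validate_map(map, truth2) # pred - obs = (1, -1)
  expect_equal(rep$rmse, 1)
  expect_equal(rep$bias, 0)

  masked <- new_map_for_test(values = rep(NA_real_, 4))
  expect_error(validate_map(masked, truth),
               class = "rededge_empty_overlap_error")
})

test_that("per-class breakdown and class-mean aggregation work", {
  map <- new_map_for_test(values = c(1, 2, 3, 5))
  truth <- tibble::tibble(pixel_row = 0:3, pixel_col = 0L,
                          value = c(1, 3, 3, 3),
                          class_label = c("a", "a", "b", "b"))
  rep <- validate_map(map, truth)
  expect_equal(sort(rep$per_class$class_label), c("a", "b"))
  agg <- validate_map(map, truth, aggregate = "class_mean")
  # class means: pred (1.5, 4) vs obs (2, 3)
  expect_equal(agg$rmse, sqrt(mean(c(-0.5, 1)^2)))
  expect_equal(agg$n, 2)
})

test_that("map agreement is exact on identity and constant offsets", {
  map <- new_map_for_test(values = c(0.2, 0.4, 0.6, 0.8))
  rep <- map_agreement(map, map)
  expect_equal(rep$r, 1)
  expect_equal(rep$rmse, 0)
  shifted <- dplyr::mutate(map, value = value + 0.4)
  rep <- map_agreement(shifted, map)
  expect_equal(rep$bias, 0.4)
  expect_equal(rep$rmse, 0.4)
  expect_equal(rep$r, 1)
  expect_equal(nrow(rep$pairs), 4)
})
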