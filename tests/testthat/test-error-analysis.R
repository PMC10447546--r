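# MAE/MSE/RMSE/MAPE, Bland-Altman, stratified reporting, distribution
# comparison, and the printed-table consistency validators.

pairs_of <- function(actual, predicted, ...) {
  tibble::tibble(subject_id = sprintf("S%02d", seq_along(actual)),
                 actual_mm = actual, predicted_mm = predicted, ...)
}

test_that("error metrics reproduce hand computations", {
  m1 <- error_metrics(pairs_of(100, 98))
  expect_equal(unlist(m1[c("mae", "mse", "rmse", "mape")]),
               c(mae = 2, mse = 4, rmse = 2, mape = 2))

  m2 <- error_metrics(pairs_of(c(50, 80), c(55, 76)))
  expect_equal(m2$mae, 4.5)
  expect_equal(m2$mse, 20.5)
  expect_equal(m2$rmse, sqrt(20.5))
  expect_equal(m2$mape, 7.5)

  same <- error_metrics(pairs_of(c(10, 20), c(10, 20)))
  expect_true(all(unlist(same[c("mae", "mse", "rmse", "mape")]) == 0))

  expect_error(error_metrics(pairs_of(numeric(0), numeric(0))),
               class = "iriscal_validation_error")
  expect_error(error_metrics(pairs_of(c(10, -5), c(9, 4))),
               class = "iriscal_validation_error", regexp = "S02")
})

test_that("Bland-Altman bias and limits of agreement", {
  const <- bland_altman(pairs_of(c(10, 20, 30), c(7, 17, 27)))
  expect_equal(const$stats$bias, 3)
  expect_equal(const$stats$sd_diff, 0)
  expect_equal(const$stats$loa_lower, 3)
  expect_equal(const$stats$loa_upper, 3)

  two <- bland_altman(pairs_of(c(11, 9), c(10, 10)))
  expect_equal(two$stats$bias, 0)
  expect_equal(two$stats$sd_diff, sqrt(2))
  expect_equal(two$stats$loa_upper, 1.96 * sqrt(2))

  expect_error(bland_altman(pairs_of(10, 9)),
               class = "iriscal_validation_error")
})

test_that("metric identities hold on random inputs", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(2:50, 1)
      actual <- runif(n, 40, 120)
      predicted <- actual + rnorm(n, 0, 5)
      m <- error_metrics(pairs_of(actual, predicted))
      expect_equal(m$rmse, sqrt(m$mse), tolerance = 1e-12)
      expect_lte(m$mae, m$rmse + 1e-12)
      expect_lte(m$rmse, max(abs(actual - predicted)) + 1e-12)
      ba <- bland_altman(pairs_of(actual, predicted))$stats
      expect_equal(ba$loa_upper - ba$loa_lower, 3.92 * ba$sd_diff,
                   tolerance = 1e-12)
      expect_gte(ba$loa_upper, ba$bias)
      expect_lte(ba$loa_lower, ba$bias)
    }
  })
})

test_that("stratified report degenerates to the pooled result", {
  withr::with_seed(31, {
    df <- pairs_of(runif(30, 50, 110), runif(30, 50, 110),
                   dimension = rep(c("horizontal", "vertical"), 15),
                   sex = "female")
  })
  rep1 <- stratified_report(df, strata = "sex")
  pooled <- stratified_report(df)
  expect_equal(dplyr::select(rep1$by_stratum, -"sex"), pooled$by_stratum)
  expect_equal(glance(rep1), glance(pooled))

  df2 <- dplyr::mutate(df, sex = rep(c("female", "male"), each = 15))
  rep2 <- stratified_report(df2, strata = "sex")
  expect_equal(sum(rep2$by_stratum$n), nrow(df2))
  # identity on the report invariants
  expect_equal(glance(rep2)$rmse, sqrt(glance(rep2)$mse))
})

test_that("equal-noise strata have statistically indistinguishable MAPEs", {
  withr::with_seed(41, {
    n <- 400
    actual <- runif(2 * n, 60, 100)
    predicted <- actual * (1 + rnorm(2 * n, 0, 0.03))
    df <- pairs_of(actual, predicted,
                   dimension = "horizontal",
                   sex = rep(c("female", "male"), each = n))
  })
  rep <- stratified_report(df, strata = "sex")
  by <- rep$by_stratum
  se <- sqrt(sum(by$mape_sd^2 / by$n))
  expect_lt(abs(diff(by$mape_mean)), 2 * se)
})

test_that("distribution comparison flags degenerate differences", {
  df <- pairs_of(c(60, 70, 80), c(60, 70, 80), dimension = "horizontal")
  cmp <- compare_distributions(df)
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)

  withr::with_seed(51, {
    actual <- runif(94, 80, 110)
  })
  shifted <- pairs_of(actual, actual + 5, dimension = "horizontal")
  cmp2 <- compare_distributions(shifted)
  expect_lt(cmp2$p_value, 0.001)
  expect_equal(cmp2$actual_min, min(actual))
  expect_equal(cmp2$predicted_max, max(actual) + 5)
})

test_that("published error tables satisfy RMSE^2 = MSE within rounding", {
  tab <- readr::read_csv(
    system.file("extdata", "published_error_summary.csv", package = "iriscal"),
    show_col_types = FALSE)
  checked <- validate_error_summary(tab)
  expect_true(all(checked$consistent))
  # sanity: the validator does reject a corrupted row
  bad <- validate_error_summary(dplyr::mutate(tab, mse = .data$mse + 1))
  expect_false(any(bad$consistent))
})
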