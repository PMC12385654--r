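test_that("maturity index interpolates between calibration endpoints", {
  expect_equal(maturity_index(5.37, 5.37, 23.54), 0)
  expect_equal(maturity_index(23.54, 5.37, 23.54), 100)
  expect_equal(maturity_index(14.455, 5.37, 23.54), 50, tolerance = 1e-10)
  expect_error(maturity_index(1, 2, 2), "degenerate")

  # affine invariance: rescaling indicator and calibration together
  y <- 14.455
  expect_equal(maturity_index(3 * y + 7, 3 * 5.37 + 7, 3 * 23.54 + 7),
               maturity_index(y, 5.37, 23.54))
})

test_that("SSC and Vc maturity calibrations evaluate as calibrated", {
  expect_equal(maturity_from_ssc(0), 3.958)
  expect_equal(maturity_from_ssc(15.3411), 0, tolerance = 1e-3)
  expect_equal(maturity_from_ssc(23.54), -2.115, tolerance = 1e-3)

  expect_equal(maturity_from_vc(0), -0.434)
  expect_equal(maturity_from_vc(1.8312), 0, tolerance = 1e-3)
  expect_equal(maturity_from_vc(35.16), 7.899, tolerance = 1e-3)
})

test_that("titratable acidity follows the titration formula", {
  expect_equal(titratable_acidity(200, 0.1, 2, 2, 10, 20), 0)
  base <- titratable_acidity(200, 0.1, 2.5, 0.5, 10, 20)
  expect_equal(base, 1.34, tolerance = 1e-10)
  expect_equal(titratable_acidity(200, 0.1, 2.5, 0.5, 10, 40), base / 2)
  expect_error(titratable_acidity(200, 0.1, 2.5, 0.5, 0, 20), "positive")
})

test_that("rmse behaves like a rooted quadratic error", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3) + 0.7), 0.7)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3), tolerance = 1e-4)
  # linear scaling of a uniform error
  expect_equal(rmse(c(0, 0), c(3, 3)), 3 * rmse(c(0, 0), c(1, 1)))
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("r_squared matches the classical 1 - SSE/SST definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)
  obs <- c(4, 7, 2, 9, 5)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    m <- rnorm(30)
    p <- m + rnorm(30, sd = 0.3)
    classical <- 1 - sum((m - p)^2) / sum((m - mean(m))^2)
    expect_equal(r_squared(m, p), classical, tolerance = 1e-12)
  }
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("MAPE and NRMSE use the documented definitions", {
  expect_equal(mape(c(1, 2), c(1, 2)), 0)
  expect_equal(mape(10, 11), 10)
  expect_equal(nrmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3) / 2, tolerance = 1e-4)
  expect_error(mape(c(0, 1), c(1, 1)), "zero")
  expect_error(nrmse(c(2, 2), c(1, 1)), "constant")

  m <- fit_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_named(m, c("r2", "rmse", "mape", "nrmse"))
  expect_equal(m$nrmse, m$rmse / 2)
})
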