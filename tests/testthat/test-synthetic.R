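test_that("the packaged 40-run experiment loads and validates", {
  t2 <- load_table2()
  expect_equal(nrow(t2), 40)
  expect_named(t2, c("x1", "x2", "x3", resp_cols))
  expect_equal(as.double(t2[1, ]),
               c(0.66, 0.51, 0.18, 14.08, 6.25, 1.76, 22.23))
  x <- as.matrix(t2[, 1:3])
  expect_true(all(x >= 0 & x <= 1))
  expect_false(anyNA(t2))
})

test_that("surface-generated data reproduces the truth at zero noise", {
  design <- random_lhs(15, 3, seed = 5)
  clean <- generate_from_rsm(design, noise_sd = 0)
  direct <- rsm_evaluate(eq15_surfaces(), design)
  expect_lt(max(abs(as.matrix(clean[, resp_cols]) - as.matrix(direct))), 1e-12)

  a <- generate_from_rsm(design, noise_sd = 2, seed = 42)
  b <- generate_from_rsm(design, noise_sd = 2, seed = 42)
  expect_identical(a, b)
  expect_error(generate_from_rsm(design, noise_sd = -1), "non-negative")
})

test_that("noise has the requested standard deviation at scale", {
  design <- random_lhs(200, 3, seed = 6)
  big <- dplyr::bind_rows(lapply(1:50, function(i) {
    generate_from_rsm(design, noise_sd = 2, seed = i)
  }))
  truth <- dplyr::bind_rows(replicate(50, rsm_evaluate(eq15_surfaces(), design),
                                      simplify = FALSE))
  res_sd <- sd(big$ssc - truth$ssc)
  expect_gt(res_sd, 1.9)
  expect_lt(res_sd, 2.1)
})

test_that("kinetic temperature profiles peak at 8 degrees and anchor exactly", {
  prof <- generate_kinetic_profiles("temperature", grid = seq(-4, 24, by = 0.5))
  at8 <- prof[prof$temperature == 8, ]
  expect_equal(at8$ssc[1], 24.95)
  expect_equal(at8$vc[1], 28.37)
  expect_lte(max(prof$ssc), 24.95)
  expect_lte(max(prof$vc), 28.37)
  ordered <- prof[order(prof$temperature), ]
  expect_true(all(diff(ordered$hardness) < 0)) # strictly decreasing with temperature
})

test_that("kinetic time profiles peak on day 4 and day 8 as observed", {
  prof <- generate_kinetic_profiles("time", grid = c(0, 2, 4, 6, 8, 12, 20, 28))
  expect_equal(prof$hardness[prof$time == 4], 1636.54)
  expect_equal(prof$vc[prof$time == 4], 35.16)
  expect_equal(prof$ssc[prof$time == 8], 23.54)
  expect_equal(prof$ta[prof$time == 8], 1.65)
  expect_equal(which.max(prof$hardness), which(prof$time == 4))
  expect_equal(which.max(prof$ssc), which(prof$time == 8))
})

test_that("maturity profiles fall for hardness/TA and are V-shaped for Vc", {
  prof <- generate_kinetic_profiles("maturity", grid = seq(20, 90, by = 2))
  expect_true(all(diff(prof$hardness) < 0))
  expect_true(all(diff(prof$ta) < 0))
  expect_true(all(diff(prof$ssc) >= 0))
  expect_equal(max(prof$vc), 26.89) # green-stage peak
  dvc <- diff(prof$vc)
  turn <- which(dvc > 0)[1]
  expect_true(all(dvc[seq_len(turn - 1)] <= 0)) # falls, then rises: V shape
  expect_true(any(dvc > 0))

  expect_error(generate_kinetic_profiles("maturity", grid = c(10, 50)), "range")
})

test_that("quadratic fits on noise-free synthetic data close the loop", {
  data <- generate_from_rsm(random_lhs(40, 3, seed = 12), noise_sd = 0)
  fit <- fit_quadratic_rsm(data)
  expect_lt(max(abs(fit$coefficients - eq15_surfaces()$coefficients)), 1e-8)
})
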