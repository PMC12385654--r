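# single-term quadratic surfaces used as known predictors
term_surface <- function(term, value = 1) {
  co <- matrix(0, 10, 1, dimnames = list(NULL, "y"))
  terms <- c("(Intercept)", "x1", "x2", "x3", "x1^2", "x2^2", "x3^2",
             "x1:x2", "x1:x3", "x2:x3")
  co[match(term, terms), 1] <- value
  quadratic_rsm(co)
}

test_that("main effects isolate each factor's own trend", {
  p1 <- term_surface("x1", 3)
  me <- main_effects(p1, n_levels = 5, n_background = 32)
  x1c <- dplyr::filter(me, factor == "x1")
  expect_equal(x1c$mean, 3 * x1c$level, tolerance = 1e-9)
  for (f in c("x2", "x3")) {
    const <- dplyr::filter(me, factor == f)
    expect_lt(diff(range(const$mean)), 1e-9)
  }

  p2 <- term_surface("x2^2")
  me2 <- main_effects(p2, n_levels = 5, n_background = 32)
  x2c <- dplyr::filter(me2, factor == "x2")
  expect_equal(x2c$mean, x2c$level^2, tolerance = 1e-9)
})

test_that("main effects of the published hardness surface match a dense-grid average", {
  rsm <- eq15_surfaces()
  me <- main_effects(rsm, n_levels = 5, n_background = 512)
  x1c <- dplyr::filter(me, response == "hardness", factor == "x1")

  # oracle: average the polynomial over a dense midpoint grid of (x2, x3)
  g <- as.matrix(expand.grid(x2 = (seq_len(101) - 0.5) / 101,
                             x3 = (seq_len(101) - 0.5) / 101))
  oracle <- vapply(x1c$level, function(l) {
    pts <- data.frame(x1 = l, x2 = g[, 1], x3 = g[, 2])
    mean(rsm_evaluate(rsm, pts)$hardness)
  }, double(1))
  rng <- diff(range(oracle))
  expect_lt(max(abs(x1c$mean - oracle)) / rng, 0.01)

  # and the analytic closed form for the slope structure of the x1 curve
  co <- rsm$coefficients[, "hardness"]
  analytic <- co["(Intercept)"] + co["x2"] * 0.5 + co["x3"] * 0.5 +
    co["x2^2"] / 3 + co["x3^2"] / 3 + co["x2:x3"] * 0.25 +
    (co["x1"] + 0.5 * (co["x1:x2"] + co["x1:x3"])) * x1c$level +
    co["x1^2"] * x1c$level^2
  expect_lt(max(abs(x1c$mean - analytic)) / rng, 0.01)
})

test_that("term contributions are signed shares summing to 100", {
  one <- quadratic_rsm(matrix(c(0, 2, 0, 0, 0, 0, 0, 0, 0, 0), ncol = 1,
                              dimnames = list(NULL, "y")))
  tc1 <- term_contributions(one)
  expect_equal(tc1$percent[tc1$term == "x1"], 100)
  expect_equal(tc1$sign[tc1$term == "x1"], 1)

  two <- quadratic_rsm(matrix(c(5, 1, -1, 0, 0, 0, 0, 0, 0, 0), ncol = 1,
                              dimnames = list(NULL, "y")))
  tc2 <- term_contributions(two)
  expect_equal(tc2$percent[tc2$term %in% c("x1", "x2")], c(50, 50))
  expect_equal(tc2$sign[tc2$term == "x2"], -1)

  full <- term_contributions(eq15_surfaces())
  sums <- dplyr::summarise(dplyr::group_by(full, response),
                           total = sum(percent))
  expect_equal(sums$total, rep(100, 4), tolerance = 1e-6)
  expect_true(all(full$percent >= 0))

  # invariance under uniform response rescaling
  scaled <- term_contributions(quadratic_rsm(3 * eq15_surfaces()$coefficients))
  expect_equal(scaled$percent, full$percent)

  zero <- quadratic_rsm(matrix(c(5, rep(0, 9)), ncol = 1,
                               dimnames = list(NULL, "y")))
  expect_error(term_contributions(zero), "undefined")
})

test_that("the hardness decomposition is dominated by temperature, negatively", {
  tc <- dplyr::filter(term_contributions(eq15_surfaces()), response == "hardness")
  expect_identical(tc$term[which.max(tc$percent)], "x1")
  expect_identical(tc$sign[tc$term == "x1"], -1)
  expect_equal(tc$percent[tc$term == "x1"], 37.23, tolerance = 0.05)
  # signs equal the signs of the printed coefficients
  co <- eq15_surfaces()$coefficients[-1, "hardness"]
  expect_equal(tc$sign, unname(sign(co)))
})
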