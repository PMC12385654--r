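test_that("the Gaussian basis is 1 at the center and decays with distance", {
  expect_equal(gaussian_basis(c(0.3, 0.4), c(0.3, 0.4), 1), 1)
  # squared distance equal to 2 * width^2 gives exp(-1)
  expect_equal(gaussian_basis(sqrt(2) * 0.5, 0, width = 0.5), exp(-1),
               tolerance = 1e-12)
  dists <- seq(0, 2, by = 0.1)
  vals <- vapply(dists, function(r) gaussian_basis(r, 0, 0.7), double(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(gaussian_basis(1, 0, 0), "positive")
})

test_that("RBF prediction is the weighted sum of basis responses", {
  net <- structure(
    list(centers = rbind(1, 2), width = 1,
         weights = matrix(c(1, 1), 2, 1), ridge = 1e-10, cv = NULL),
    class = "rbf_surrogate", inputs = "x1", responses = "y"
  )
  # centers at distance 1 and 2 from x = 0
  expect_equal(predict(net, data.frame(x1 = 0))$y,
               exp(-0.5) + exp(-2), tolerance = 1e-4)

  net$weights <- matrix(0, 2, 1)
  expect_equal(predict(net, data.frame(x1 = 0.5))$y, 0)

  single <- structure(
    list(centers = matrix(c(0.2, 0.8), 1), width = 2,
         weights = matrix(c(3, -1), 1, 2), ridge = 1e-10, cv = NULL),
    class = "rbf_surrogate", inputs = c("x1", "x2"), responses = c("a", "b")
  )
  at_center <- predict(single, data.frame(x1 = 0.2, x2 = 0.8))
  expect_equal(as.double(at_center), c(3, -1))
})

test_that("RBF training interpolates at the regularization floor", {
  t2 <- load_table2()
  for (w in c(0.1, 0.5)) {
    fit <- rbf_train(t2, width = w)
    expect_lt(rel_resid(predict(fit, t2), t2[resp_cols]), 1e-6)
  }

  # constant targets are reproduced at the training points
  const <- t2
  const$hardness <- 7
  fitc <- rbf_train(const, responses = "hardness", width = 0.5)
  expect_equal(predict(fitc, const)$hardness, rep(7, 40), tolerance = 1e-6)
})

test_that("cross-validated RBF recovers a smooth function on a grid", {
  g <- expand.grid(x1 = seq(0, 1, length.out = 5),
                   x2 = seq(0, 1, length.out = 5),
                   x3 = seq(0, 1, length.out = 5))
  g$resp <- 2 + g$x1 - 0.5 * g$x2^2 + g$x1 * g$x3
  set.seed(31)
  train_idx <- sample(125, 90)
  fit <- rbf_train(g[train_idx, ], responses = "resp")
  pred <- predict(fit, g[-train_idx, ])
  expect_gt(r_squared(g$resp[-train_idx], pred$resp), 0.999)
  expect_true(fit$width %in% fit$cv$width)
})

test_that("duplicate training inputs raise the floor with a warning", {
  t2 <- load_table2()
  dup <- rbind(t2, t2[1, ])
  expect_warning(fit <- rbf_train(dup, width = 0.5), "duplicate")
  expect_gte(fit$ridge, 1e-6)
})
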