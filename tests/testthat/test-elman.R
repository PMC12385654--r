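test_that("the forward pass implements the context recursion exactly", {
  net <- list(w_context = matrix(0.5), w_input = matrix(1), w_output = matrix(2))
  out <- elman_forward(net, matrix(c(1, 0)))
  # hand recursion: tanh(1) = 0.7616; tanh(0.5 * 0.7616) = 0.3633
  expect_equal(as.double(out$outputs), c(1.5232, 0.7266), tolerance = 1e-3)

  zero <- list(w_context = matrix(0, 3, 3),
               w_input = matrix(0, 3, 2),
               w_output = matrix(0, 2, 3))
  res <- elman_forward(zero, matrix(runif(10), 5, 2))
  expect_true(all(res$outputs == 0))

  # context after the run equals the final hidden state, and each step's
  # hidden state feeds the next step
  set.seed(5)
  net2 <- list(w_context = matrix(rnorm(9, sd = 0.3), 3, 3),
               w_input = matrix(rnorm(6, sd = 0.3), 3, 2),
               w_output = matrix(rnorm(3, sd = 0.3), 1, 3))
  u <- matrix(runif(8), 4, 2)
  res2 <- elman_forward(net2, u)
  expect_equal(res2$context, res2$hidden[4, ])
  manual_step2 <- tanh(as.vector(net2$w_context %*% res2$hidden[1, ] +
                                   net2$w_input %*% u[2, ]))
  expect_equal(res2$hidden[2, ], manual_step2)

  expect_equal(nrow(elman_forward(net, matrix(numeric(0), 0, 1))$outputs), 0)
})

test_that("gradient training reduces the error and records its stop reason", {
  t2 <- load_table2()
  fit <- elman_train(t2, max_epochs = 200, seed = 1)
  expect_lte(fit$trace$mse[fit$epochs_run], fit$trace$mse[1])
  expect_identical(fit$stop_reason, "max_epochs")

  # a loose error tolerance triggers the early stop on the first epoch
  early <- elman_train(t2, max_epochs = 200, error_tol = 1e3, seed = 1)
  expect_identical(early$epochs_run, 1L)
  expect_identical(early$stop_reason, "error_tol")
})

test_that("the network learns a simple linear response", {
  d <- as.data.frame(random_lhs(50, 3, seed = 3))
  d$target <- d$x1
  fit <- elman_train(d, responses = "target", seed = 1)
  pred <- predict(fit, d)
  expect_lt(mean((pred$target - d$target)^2), 1e-3)
})

test_that("training is reproducible by seed and standardization round-trips", {
  t2 <- load_table2()
  a <- elman_train(t2, max_epochs = 30, seed = 11)
  b <- elman_train(t2, max_epochs = 30, seed = 11)
  expect_identical(a$w_output, b$w_output)
  expect_identical(predict(a, t2), predict(b, t2))

  # per-row context reset yields order-independent predictions
  p1 <- predict(a, t2[1:5, ], reset = "row")
  p2 <- predict(a, t2[5:1, ], reset = "row")
  expect_equal(as.matrix(p1), as.matrix(p2[5:1, ]), ignore_attr = TRUE)
})
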