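test_that("the constriction factor limits velocities for large phi", {
  expect_equal(constriction_factor(1.5, 1.5), 1)
  expect_equal(constriction_factor(2, 2.1), 0.7299, tolerance = 1e-3)
  set.seed(3)
  for (i in 1:50) {
    chi <- constriction_factor(runif(1, 0, 4), runif(1, 0, 4))
    expect_gt(chi, 0)
    expect_lte(chi, 1)
  }
})

test_that("archive insertion maintains a bounded non-dominated set", {
  arch <- list(positions = NULL, objectives = NULL)
  arch <- archive_insert(arch, c(0.5), c(1, 1))
  # dominated candidate rejected
  arch2 <- archive_insert(arch, c(0.1), c(0.5, 0.5))
  expect_equal(nrow(arch2$objectives), 1)
  expect_equal(as.double(arch2$objectives[1, ]), c(1, 1))
  # dominating candidate replaces everything
  arch3 <- archive_insert(arch2, c(0.9), c(2, 2))
  expect_equal(nrow(arch3$objectives), 1)
  expect_equal(as.double(arch3$objectives[1, ]), c(2, 2))

  # capacity eviction drops the most crowded member and keeps the extremes
  arch <- list(positions = NULL, objectives = NULL)
  f1 <- seq(0, 1, length.out = 10)
  for (i in seq_along(f1)) {
    arch <- archive_insert(arch, f1[i], c(f1[i], 1 - f1[i]), capacity = 3)
  }
  expect_equal(nrow(arch$objectives), 3)
  expect_true(oracle_mutually_nondominated(arch$objectives))
  expect_true(all(c(0, 1) %in% arch$objectives[, 1]))

  expect_error(archive_insert(arch, 0.5, c(NaN, 1)), "finite")
})

test_that("SMPSO recovers the analytic front of a bi-objective toy problem", {
  prob <- moo_problem(function(x) c(x, 1 - x^2), n_var = 1,
                      objective_names = c("f1", "f2"))
  arch <- run_smpso(prob, smpso_config(12, 50, seed = 4))
  expect_true(oracle_mutually_nondominated(arch$objectives))
  # every archived point lies on f2 = 1 - f1^2 and the front is covered
  expect_lt(max(abs(arch$objectives[, 2] - (1 - arch$objectives[, 1]^2))), 1e-2)
  expect_gt(diff(range(arch$objectives[, 1])), 0.5)
})

test_that("SMPSO is reproducible and respects the constant-problem degeneracy", {
  prob <- moo_problem(function(x) c(1, 2), n_var = 2)
  arch <- run_smpso(prob, smpso_config(6, 5, seed = 1))
  expect_equal(nrow(arch$objectives), 1)

  prob2 <- moo_problem(function(x) c(sum(x), -sum(x^2)), n_var = 2)
  a <- run_smpso(prob2, smpso_config(8, 10, seed = 7))
  b <- run_smpso(prob2, smpso_config(8, 10, seed = 7))
  expect_identical(a$objectives, b$objectives)
  expect_identical(a$positions, b$positions)

  expect_error(run_smpso(moo_problem(function(x) c(NA_real_, 1), 1),
                         smpso_config(4, 2, seed = 1)), "non-finite")
})

test_that("select_optimal picks the knee and breaks ties deterministically", {
  arch <- structure(list(
    positions = matrix(c(0.1, 0.5, 0.9), 3, 1),
    objectives = cbind(f1 = c(0, 0.9, 1), f2 = c(1, 0.9, 0)),
    crowding = c(Inf, 1, Inf)
  ), class = "pareto_archive")
  # normalized distances: extremes are 1 away from the ideal, the knee ~0.14
  expect_equal(select_optimal(arch)$x1, 0.5)

  tie <- structure(list(
    positions = matrix(c(0.2, 0.8), 2, 1),
    objectives = cbind(f1 = c(0, 1), f2 = c(1, 0)),
    crowding = c(2, 1)
  ), class = "pareto_archive")
  expect_equal(select_optimal(tie)$x1, 0.2) # equal distance; larger crowding wins

  singleton <- structure(list(
    positions = matrix(0.3, 1, 1),
    objectives = cbind(f1 = 5, f2 = 5),
    crowding = Inf
  ), class = "pareto_archive")
  expect_equal(select_optimal(singleton)$x1, 0.3)
  expect_error(select_optimal(structure(list(objectives = NULL),
                                        class = "pareto_archive")), "empty")
})

test_that("scenario queries freeze time and return self-consistent optima", {
  rsm <- eq15_surfaces()
  res <- scenario_query(rsm, time_days = 10,
                        config = smpso_config(8, 15, seed = 6))
  expect_equal(res$time, 10)
  space <- wolfberry_factors()
  expect_gte(res$temperature, space$lower[1])
  expect_lte(res$temperature, space$upper[1])
  expect_gte(res$maturity, space$lower[3])
  expect_lte(res$maturity, space$upper[3])

  # the reported qualities equal the surface evaluated at the reported point
  unit <- normalize_points(res[, c("temperature", "time", "maturity")], space)
  direct <- rsm_evaluate(rsm, unit)
  expect_equal(as.double(res[, resp_cols]), as.double(direct), tolerance = 1e-9)

  expect_error(storage_problem(rsm, frozen = c(time = 40)), "range")
  expect_error(storage_problem(rsm, frozen = c(temperature = 5, time = 10,
                                               maturity = 50)), "free")
})
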