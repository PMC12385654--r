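test_that("random Latin hypercubes are stratified, seeded and in-range", {
  d1 <- random_lhs(1, 3, seed = 1)
  expect_equal(nrow(d1), 1)
  expect_true(all(d1 >= 0 & d1 <= 1))

  for (s in 1:5) {
    des <- random_lhs(10, 2, seed = s)
    expect_true(is_latin(des))
  }
  expect_identical(random_lhs(10, 2, seed = 4), random_lhs(10, 2, seed = 4))
  expect_false(isTRUE(all.equal(as.matrix(random_lhs(10, 2, seed = 1)),
                                as.matrix(random_lhs(10, 2, seed = 2)))))
})

test_that("neighborhood LHS stays inside the clipped search box", {
  pts <- lhs_neighborhood(c(0.5, 0.5), radius = 0.1, count = 4, seed = 1)
  expect_equal(nrow(pts), 4)
  expect_lte(max(abs(sweep(pts, 2, c(0.5, 0.5)))), 0.1)

  corner <- lhs_neighborhood(c(0, 0), radius = 0.2, count = 10, seed = 2)
  expect_true(all(corner >= 0 & corner <= 0.2))

  tiny <- lhs_neighborhood(c(0.3, 0.7), radius = 1e-9, count = 3, seed = 3)
  expect_lt(max(abs(sweep(tiny, 2, c(0.3, 0.7)))), 1e-8)
})

test_that("uniformity report quantifies spread and stratification", {
  two <- rbind(c(0.25, 0.25), c(0.75, 0.75))
  rep2 <- uniformity_report(two)
  expect_equal(rep2$min_pairwise_distance, sqrt(0.5), tolerance = 1e-10)

  lhs_rep <- uniformity_report(random_lhs(15, 3, seed = 5))
  expect_true(all(lhs_rep$bin_occupancy == 1))
  expect_gt(lhs_rep$centered_l2_discrepancy, 0)

  dup <- rbind(c(0.2, 0.2), c(0.2, 0.2), c(0.8, 0.8))
  expect_equal(uniformity_report(dup)$min_pairwise_distance, 0)

  expect_error(uniformity_report(matrix(0.5, 1, 2)), "fewer than 2")
})

centered_discrepancy_of <- function(m) uniformity_report(m)$centered_l2_discrepancy

test_that("centered L2 discrepancy prefers a stratified design over a clump", {
  set.seed(21)
  clump <- matrix(runif(40, 0.4, 0.6), 20, 2)
  spread <- as.matrix(random_lhs(20, 2, seed = 8))
  expect_lt(centered_discrepancy_of(spread), centered_discrepancy_of(clump))
})

test_that("non-dominated ranking agrees with the brute-force oracle", {
  expect_identical(nondominated_rank(matrix(c(1, 2), 1)), 1L)
  expect_identical(nondominated_rank(rbind(c(2, 2), c(1, 1))), c(1L, 2L))
  expect_identical(nondominated_rank(matrix(numeric(0), 0, 2)), integer(0))

  set.seed(11)
  for (m in c(2, 3, 4)) {
    obj <- matrix(runif(50 * m), 50, m)
    expect_identical(nondominated_rank(obj), oracle_ranks(obj))
  }
  # ties and duplicated points
  obj <- rbind(c(1, 1), c(1, 1), c(0, 2), c(2, 0), c(0, 0))
  expect_identical(nondominated_rank(obj), oracle_ranks(obj))
})

test_that("the LHS-MOEA conserves population size and improves monotonically", {
  res <- run_lhs_moea(function(x) c(sum(x), -sum(x)), n_var = 2,
                      config = moea_config(4, 1, seed = 1))
  expect_length(res$individuals, 4)

  sphere <- run_lhs_moea(function(x) -sum(x^2), n_var = 3,
                         config = moea_config(12, 15, seed = 2))
  expect_true(all(diff(sphere$trace[, 1]) >= 0)) # elitism: best never worsens
  expect_gt(max(sphere$trace[, 1]), sphere$trace[1, 1]) # and actually improves

  front <- sphere$objectives[sphere$rank == 1L, , drop = FALSE]
  expect_true(oracle_mutually_nondominated(front))
})

test_that("MOEA raises an evaluation error on non-finite objectives", {
  expect_error(
    run_lhs_moea(function(x) NaN, n_var = 2, config = moea_config(4, 1, seed = 1)),
    "non-finite objective"
  )
})

test_that("optimized designs are Latin, reproducible and beat random designs", {
  cfg <- moea_config(16, 12, seed = 9)
  des <- optimize_design(20, 3, cfg)
  expect_true(is_latin(des))
  expect_identical(as.matrix(des), as.matrix(optimize_design(20, 3, cfg)))

  u <- attr(des, "uniformity")
  md <- replicate(60, uniformity_report(random_lhs(20, 3))$min_pairwise_distance)
  expect_gte(u$min_pairwise_distance, stats::median(md))
})
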