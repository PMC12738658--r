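test_that("trajectory-pair eCDF matches brute-force pair enumeration", {
  S <- trajectory_set(c(0, 1), matrix(c(0, 1), 2, 1))
  St <- trajectory_set(c(0, 1), matrix(c(0, 2), 2, 1))
  bins <- radius_bins(c(0.5, 1.5, 2.5))
  y <- pairwise_ecdf_trajectories(S, St, bins)
  # pair distances are {0, 2, 1, 1}
  expect_equal(y$y, c(1 / 4, 3 / 4, 1))

  # random instances against an independent double-loop oracle
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(8 * 3), 8, 3)
    B <- matrix(rnorm(8 * 3), 8, 3)
    R <- sort(runif(6, 0.1, 4))
    brute <- vapply(R, function(r) {
      cnt <- 0
      for (i in 1:8) for (j in 1:8) {
        if (sqrt(sum((A[i, ] - B[j, ])^2)) < r) cnt <- cnt + 1
      }
      cnt / 64
    }, numeric(1))
    y2 <- pairwise_ecdf_trajectories(trajectory_set(1:8, A),
                                     trajectory_set(1:8, B),
                                     radius_bins(R))
    expect_equal(y2$y, brute, tolerance = 1e-12)
  }
})

test_that("eCDF vectors are monotone, bounded, and symmetric in the two sets", {
  set.seed(42)
  A <- matrix(rnorm(30), 10, 3)
  B <- matrix(rnorm(30), 10, 3)
  bins <- radius_bins(sort(runif(8, 0.05, 5)))
  y_ab <- pairwise_ecdf_trajectories(trajectory_set(1:10, A),
                                     trajectory_set(1:10, B), bins)
  y_ba <- pairwise_ecdf_trajectories(trajectory_set(1:10, B),
                                     trajectory_set(1:10, A), bins)
  expect_identical(y_ab$y, y_ba$y)
  expect_true(all(y_ab$y >= 0 & y_ab$y <= 1))
  expect_true(all(diff(y_ab$y) >= 0))
  # a first radius beyond the diameter counts every pair
  big <- radius_bins(c(100, 200))
  expect_equal(pairwise_ecdf_trajectories(trajectory_set(1:10, A),
                                          trajectory_set(1:10, B), big)$y,
               c(1, 1))
  # partial observation restricts the norm to the masked components
  y_first <- pairwise_ecdf_trajectories(trajectory_set(1:10, A),
                                        trajectory_set(1:10, B), bins,
                                        components = 1)
  d1 <- abs(outer(A[, 1], B[, 1], "-"))
  expect_equal(y_first$y,
               vapply(bins$R, function(r) mean(d1 < r), numeric(1)))
  expect_error(pairwise_ecdf_trajectories(
    trajectory_set(1:10, A), trajectory_set(1:10, B[, 1:2]), bins),
    class = "cil_validation_error")
})

test_that("pattern distances are grid-weighted norms with the expected values", {
  expect_identical(pattern_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pattern_distance(c(0, 0), c(1, 1), "L2"), sqrt(2))
  expect_equal(pattern_distance(c(0, 0), c(1, 1), "L1"), 2)
  expect_equal(pattern_distance(c(0, -3), c(1, 1), "Linf"), 4)
  expect_equal(pattern_distance(c(0, 0), c(1, 1), "L2", cell_volume = 0.5), 1)
  set.seed(1)
  for (i in 1:5) {
    p1 <- matrix(rnorm(12), 3, 4); p2 <- matrix(rnorm(12), 3, 4)
    expect_identical(pattern_distance(p1, p2), pattern_distance(p2, p1))
    expect_gte(pattern_distance(p1, p2), 0)
  }
  expect_error(pattern_distance(c(1, 2), c(1, 2, 3)),
               class = "cil_validation_error")
})

test_that("distance-sample eCDF counts strictly below each radius", {
  y <- ecdf_patterns(c(1, 2, 3), radius_bins(c(1.5, 2.5, 3.5)))
  expect_equal(y$y, c(1 / 3, 2 / 3, 1))
  # ties at the bin edge are outside the bin
  expect_equal(ecdf_patterns(c(1, 2), radius_bins(c(1, 2)))$y, c(0, 1 / 2))
  expect_equal(ecdf_patterns(c(5, 6), radius_bins(c(1, 2)))$y, c(0, 0))
  expect_equal(ecdf_patterns(c(1, 1, 1), radius_bins(c(2, 3)))$y, c(1, 1))
  expect_error(ecdf_patterns(numeric(0), radius_bins(c(1, 2))),
               class = "cil_validation_error")
})

test_that("bin selection places radii at training-distance quantiles", {
  d <- with_seed_test(101, runif(1e4))
  bins <- select_radii(d, M = 4)
  expect_equal(bins$R, c(0.2, 0.4, 0.6, 0.8), tolerance = 0.05)
  expect_error(select_radii(rep(1, 50), M = 3),
               class = "cil_bins_degenerate_error")
  for (seed in 1:5) {
    set.seed(seed)
    b <- select_radii(rexp(200), M = 6)
    expect_true(all(diff(b$R) > 0))
    expect_true(all(b$R > 0))
  }
})
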