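test_that("subset pairing yields n_ens(n_ens-1)/2 realisations with valid moments", {
  set.seed(7)
  pats <- lapply(1:30, function(i) rnorm(16))
  ens <- pattern_ensemble(pats)
  stats <- estimate_statistics(ens, n_ens = 10, M = 5)
  expect_equal(stats$n_realisations, 45)
  expect_equal(stats$N, 3)
  expect_true(all(stats$mu >= 0 & stats$mu <= 1))
  expect_true(all(diff(stats$mu) >= 0))
  expect_true(isSymmetric(stats$sigma))
  expect_gt(min(eigen(stats$sigma)$values), 0)
})

test_that("identical subsets give zero covariance before regularisation", {
  base <- lapply(1:4, function(i) c(i, i + 1))
  pats <- rep(base, 5) # five identical copies of one 4-pattern set
  ens <- pattern_ensemble(pats)
  bins <- radius_bins(c(0.5, 1.5, 3))
  suppressWarnings(stats <- estimate_statistics(ens, n_ens = 5, N = 4,
                                                bins = bins))
  # every pair of identical subsets gives the same eCDF vector, so the
  # sample covariance vanishes and only the (tiny) ridge survives
  expect_true(all(apply(stats$realisations, 2L, var) == 0))
  expect_true(all(stats$sigma[upper.tri(stats$sigma)] == 0))
  expect_lt(max(diag(stats$sigma)), 1e-20)
})

test_that("statistics are invariant to subset order", {
  set.seed(9)
  pats <- lapply(1:24, function(i) rnorm(12))
  ens1 <- pattern_ensemble(pats)
  # permute whole blocks of 4 (the subsets), keeping within-block order
  perm <- c(5, 2, 6, 1, 4, 3)
  idx <- unlist(lapply(perm, function(b) (b - 1) * 4 + 1:4))
  ens2 <- pattern_ensemble(pats[idx])
  bins <- radius_bins(c(1, 2, 3, 4))
  s1 <- estimate_statistics(ens1, n_ens = 6, N = 4, bins = bins)
  s2 <- estimate_statistics(ens2, n_ens = 6, N = 4, bins = bins)
  expect_equal(s1$mu, s2$mu, tolerance = 1e-12)
  expect_equal(s1$sigma, s2$sigma, tolerance = 1e-12)
})

test_that("rank deficiency triggers the regularisation warning", {
  set.seed(3)
  pats <- lapply(1:9, function(i) rnorm(10))
  ens <- pattern_ensemble(pats)
  expect_warning(estimate_statistics(ens, n_ens = 3, N = 3, M = 3),
                 regexp = "rank-deficient")
  expect_error(estimate_statistics(ens, n_ens = 2, N = 3, M = 3),
               class = "cil_validation_error")
})

test_that("the Mahalanobis cost matches a dense-inverse oracle", {
  bins5 <- radius_bins(1:5 / 10)
  set.seed(11)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    S <- crossprod(A) + diag(5) * 0.1
    mu <- sort(runif(5))
    stats <- manual_stats(mu, S, bins5)
    yv <- pmin(pmax(mu + rnorm(5, sd = 0.05), 0), 1)
    yv <- cummax(yv)
    y <- ecdf_vector(yv, bins5)
    expect_equal(cil_cost(y, stats), dense_quadform(yv - mu, S),
                 tolerance = 1e-10)
  }
  # exact special cases
  stats_id <- manual_stats(rep(0.4, 5), diag(5), bins5)
  expect_equal(cil_cost(ecdf_vector(rep(0.4, 5), bins5), stats_id), 0)
  # residual along one basis direction: cost is its squared length
  y_last <- c(rep(0.4, 4), 0.9)
  expect_equal(cil_cost(ecdf_vector(y_last, bins5), stats_id), 0.25)
  expect_error(cil_cost(ecdf_vector(rep(0.5, 3), radius_bins(1:3)), stats_id),
               class = "cil_validation_error")
})

test_that("cost evaluation at a parameter is seeded and reproducible", {
  mod <- make_turing_model(grid = list(nx = 32, length = 20),
                           solver_cfg = list(max_time = 150))
  stats <- estimate_statistics_sim(mod, schnakenberg_params(), n_rep = 25,
                                   N = 4, M = 4, seed = 2)
  f1 <- cil_cost_at_parameter(schnakenberg_params(), stats, mod, seed = 5)
  f2 <- cil_cost_at_parameter(schnakenberg_params(), stats, mod, seed = 5)
  expect_identical(f1, f2)
  expect_gte(f1, 0)
  f3 <- cil_cost_at_parameter(schnakenberg_params(), stats, mod, seed = 6)
  expect_false(identical(f1, f3))
})

test_that("chi-squared calibration report behaves on known inputs", {
  costs <- with_seed_test(21, rchisq(2000, df = 10))
  cal <- chi2_calibration(costs, 10)
  expect_gt(cal$mean_ratio, 0.9)
  expect_lt(cal$mean_ratio, 1.1)
  expect_gt(cal$ks_pvalue, 0.01)
  flat <- chi2_calibration(rep(0, 100), 10)
  expect_equal(flat$mean_ratio, 0)
  expect_lt(flat$ks_pvalue, 1e-6)
})

test_that("SCIL accepts a single snapshot and is reproducible", {
  mod <- make_turing_model(grid = list(nx = 32, length = 20),
                           solver_cfg = list(max_time = 150))
  snap <- mod$simulate(schnakenberg_params(), 1, seed = 77)
  f1 <- scil_cost(schnakenberg_params(), snap, mod, N = 6, n_rep = 30,
                  M = 3, seed = 9)
  f2 <- scil_cost(schnakenberg_params(), snap, mod, N = 6, n_rep = 30,
                  M = 3, seed = 9)
  expect_identical(f1, f2)
  expect_true(is.finite(f1))
  expect_gte(as.numeric(f1), 0)
})
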