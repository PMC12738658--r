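test_that("Gaussian prior and likelihood match their quadratic forms", {
  pr <- gaussian_prior(c(1, 2), diag(2))
  expect_equal(log_prior(c(1, 2), pr), 0)
  expect_equal(log_prior(c(2, 2), pr), -0.5)
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3) * 0.1
    m <- rnorm(3); th <- rnorm(3)
    expect_equal(log_prior(th, gaussian_prior(m, S)),
                 -0.5 * dense_quadform(th - m, S), tolerance = 1e-10)
    D <- rnorm(3); pred <- rnorm(3)
    expect_equal(gaussian_loglik(D, pred, S),
                 -0.5 * dense_quadform(D - pred, S), tolerance = 1e-10)
  }
  expect_equal(gaussian_loglik(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(gaussian_loglik(3, 1, 4), -0.5) # residual 2, variance 4
  expect_error(gaussian_loglik(c(1, 2), 1, diag(2)),
               class = "cil_validation_error")
  expect_error(gaussian_prior(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               class = "cil_validation_error")
})

test_that("the posterior potential is the sum of the two penalties", {
  pr <- gaussian_prior(c(0.5), matrix(2))
  spec <- potential_spec(function(th) th^2, D = 0.25, Gamma = matrix(0.5),
                         prior = pr)
  expect_equal(potential(0.5, spec), 0) # D = M(theta) and theta = m
  # hand computation for a quadratic forward map in 1-D
  th <- 1.5
  expect_equal(potential(th, spec),
               0.5 * (0.25 - th^2)^2 / 0.5 + 0.5 * (th - 0.5)^2 / 2)
  set.seed(8)
  for (i in 1:5) {
    th <- rnorm(1)
    expect_equal(potential(th, spec),
                 -gaussian_loglik(0.25, th^2, matrix(0.5)) -
                   log_prior(th, pr))
    expect_gte(potential(th, spec), 0)
  }
  bad <- potential_spec(function(th) stop("boom"), D = 1,
                        Gamma = matrix(1), prior = pr)
  expect_warning(v <- potential(1, bad), regexp = "forward model failed")
  expect_identical(v, Inf)
})

test_that("colony log-likelihood matches the lognormal error model", {
  times <- c(0, 4, 8)
  r_true <- colony_forward_radii(colony_theta_star[c("alpha", "sigma_k",
                                                     "sigma_s")],
                                 times, r_max = 2, n_r = 80)
  # noiseless data evaluated at the generating parameters: residuals vanish
  meas <- observe_radius(r_true, 0, seed = 1, times = times)
  th_eval <- colony_theta_star
  ll <- colony_loglik(meas, th_eval, r_max = 2, n_r = 80)
  expect_equal(ll, 3 * (-log(sqrt(2 * pi) * 0.05)), tolerance = 1e-8)

  # one observation exactly one log-unit off, sigma_o = 1
  meas1 <- meas[2, ]
  meas1$r_obs <- meas1$r_true * exp(1)
  th1 <- colony_theta_star; th1["sigma_o"] <- 1
  expect_equal(colony_loglik(meas1, th1, r_max = 2, n_r = 80),
               -log(sqrt(2 * pi)) - 0.5, tolerance = 1e-8)

  # invariant to row reordering
  meas_noisy <- observe_radius(r_true, 0.1, seed = 3, times = times)
  expect_equal(colony_loglik(meas_noisy, th_eval, r_max = 2, n_r = 80),
               colony_loglik(meas_noisy[c(3, 1, 2), ], th_eval, r_max = 2,
                             n_r = 80))
})

test_that("the likelihood slice is maximised near the generating alpha", {
  times <- seq(0, 16, by = 4)
  r_true <- colony_forward_radii(colony_theta_star[c("alpha", "sigma_k",
                                                     "sigma_s")],
                                 times, r_max = 2.4, n_r = 80)
  meas <- observe_radius(r_true, 0.03, seed = 12, times = times)
  alphas <- c(0.1, 0.2, 0.3, 0.45, 0.7)
  ll <- vapply(alphas, function(a) {
    th <- colony_theta_star; th["alpha"] <- a
    colony_loglik(meas, th, r_max = 2.4, n_r = 80)
  }, numeric(1))
  expect_equal(alphas[which.max(ll)], 0.3)
})

test_that("Monte Carlo integration on the unit cube is exact and seeded", {
  expect_identical(mc_integrate(function(x) 1, n = 17, seed = 4), 1)
  est <- mc_integrate(function(x) x, n = 1e5, seed = 10)
  expect_lt(abs(est - 0.5), 4 * sqrt(1 / 12) / sqrt(1e5))
  expect_identical(mc_integrate(function(x) sum(x^2), n = 50, seed = 3, d = 2),
                   mc_integrate(function(x) sum(x^2), n = 50, seed = 3, d = 2))
  suppressWarnings(
    expect_error(mc_integrate(function(x) log(x - 2), n = 10, seed = 1),
                 class = "cil_numerical_error"))
})
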