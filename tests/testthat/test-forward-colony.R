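test_that("mass-fraction radius matches closed forms", {
  # initial ball density p = 4 pi r^2 on [0, sigma_s]: cumulative mass ~ r^3
  sol <- simulate_colony(c(alpha = 0.3, sigma_k = 0.15, sigma_s = 0.25),
                         r_max = 1, n_r = 400, t_grid = 0)
  r95 <- colony_radius(sol, 1, mass_fraction = 0.95)
  expect_equal(r95, 0.95^(1 / 3) * 0.25, tolerance = 5e-3)
  # monotone in the mass fraction, and -> support end as fraction -> 1
  fr <- vapply(c(0.5, 0.8, 0.95, 0.999999),
               function(f) colony_radius(sol, 1, f), numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_equal(fr[4], 0.25, tolerance = 2e-2)

  # uniform radial density on [0, L]: cumulative mass is linear
  L <- 2
  r <- (seq_len(500) - 0.5) * (L / 500)
  unif <- structure(list(r_grid = r, t_grid = 0,
                         n = matrix(1, 500, 1),
                         p = matrix(1, 500, 1)),
                    class = "colony_solution")
  expect_equal(colony_radius(unif, 1, 0.95), 0.95 * L, tolerance = 1e-3)

  zero <- structure(list(r_grid = r, t_grid = 0, n = matrix(0, 500, 1),
                         p = matrix(0, 500, 1)), class = "colony_solution")
  expect_error(colony_radius(zero, 1), class = "cil_validation_error")
})

test_that("zero proliferation freezes the density", {
  sol <- simulate_colony(c(alpha = 0, sigma_k = 0.1, sigma_s = 0.3),
                         r_max = 1, n_r = 100, t_grid = c(0, 5, 10))
  expect_identical(sol$n[, 1], sol$n[, 2])
  expect_identical(sol$n[, 1], sol$n[, 3])
})

test_that("density and mass are monotone and bounded", {
  sol <- simulate_colony(colony_theta_star[c("alpha", "sigma_k", "sigma_s")],
                         r_max = 2.4, n_r = 120, t_grid = seq(0, 16, by = 2))
  expect_true(all(sol$n >= 0 & sol$n <= 1))
  expect_true(all(diff(t(sol$n)) >= -1e-7)) # n non-decreasing in time
  mass <- apply(sol$p, 2L, function(p) trapz_int <- sum(p) * diff(sol$r_grid[1:2]))
  expect_true(all(diff(mass) >= -1e-10))
  rad <- vapply(seq_along(sol$t_grid), function(i) colony_radius(sol, i),
                numeric(1))
  expect_true(all(diff(rad) > 0))
})

test_that("colony solver agrees with a coarse explicit-Euler oracle", {
  th <- c(alpha = 0.4, sigma_k = 0.2, sigma_s = 0.3)
  n_r <- 60; r_max <- 1.5
  sol <- simulate_colony(th, r_max = r_max, n_r = n_r, t_grid = c(0, 2))
  # independent forward-Euler integration of the same semi-discrete system
  h <- r_max / n_r
  r <- (seq_len(n_r) - 0.5) * h
  W <- colony_kernel_matrix(r, th[["sigma_k"]])
  n <- pmin(pmax((th[["sigma_s"]] - (r - h / 2)) / h, 0), 1)
  dt <- 1e-3
  for (k in seq_len(2 / dt)) {
    n <- n + dt * th[["alpha"]] * drop(W %*% n) * (1 - n)
  }
  expect_equal(sol$n[, 2], n, tolerance = 1e-3)
})

test_that("the radial kernel reproduces the unit-mass convolution", {
  r <- (seq_len(300) - 0.5) * (3 / 300)
  W <- colony_kernel_matrix(r, 0.25)
  conv1 <- drop(W %*% rep(1, 300))
  interior <- r > 0.3 & r < 2.5
  expect_true(all(abs(conv1[interior] - 1) < 5e-3))
})

test_that("solutions self-converge under grid refinement", {
  th <- c(alpha = 0.3, sigma_k = 0.15, sigma_s = 0.25)
  r <- vapply(c(60, 240, 960),
              function(nr) colony_forward_radii(th, c(0, 10), r_max = 2.4,
                                                n_r = nr)[2],
              numeric(1))
  expect_lt(abs(r[3] - r[2]), abs(r[2] - r[1]))
  expect_lt(abs(r[3] - r[2]) / r[3], 5e-3)
})

test_that("domain overflow and invalid parameters are rejected", {
  expect_error(simulate_colony(c(alpha = 0.5, sigma_k = 0.2, sigma_s = 0.4),
                               r_max = 0.6, n_r = 60, t_grid = c(0, 20)),
               class = "cil_domain_error")
  expect_error(simulate_colony(c(alpha = 0.3, sigma_k = -1, sigma_s = 0.2),
                               t_grid = c(0, 1)),
               class = "cil_validation_error")
})

test_that("multiplicative radius observation has the stated error model", {
  r_true <- c(0.3, 0.5, 0.9)
  exact <- observe_radius(r_true, 0, seed = 1)
  expect_identical(exact$r_obs, r_true)
  expect_identical(observe_radius(r_true, 0.1, seed = 2)$r_obs,
                   observe_radius(r_true, 0.1, seed = 2)$r_obs)
  expect_false(identical(observe_radius(r_true, 0.1, seed = 2)$r_obs,
                         observe_radius(r_true, 0.1, seed = 3)$r_obs))
  # sample variance of the log over many replicates recovers sigma_o^2
  sigma_o <- 0.2
  z <- vapply(seq_len(1e4),
              function(i) log(observe_radius(1, sigma_o, seed = i)$r_obs),
              numeric(1))
  expect_equal(var(z), sigma_o^2, tolerance = 0.05)
  expect_true(all(observe_radius(r_true, 2, seed = 4)$r_obs > 0))
})
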