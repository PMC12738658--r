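test_that("potential gradients match analytic oracles and converge in h", {
  V <- function(x) 0.5 * sum(x^2)
  expect_equal(grad_potential(V, c(1, -2)), c(1, -2), tolerance = 1e-8)
  set.seed(2)
  A <- crossprod(matrix(rnorm(9), 3))
  Vq <- function(x) drop(t(x) %*% A %*% x)
  th <- rnorm(3)
  expect_equal(grad_potential(Vq, th), drop(2 * A %*% th), tolerance = 1e-6)
  # quartic test: central-difference error falls quadratically with h
  Vquart <- function(x) x^4
  err <- vapply(c(1e-2, 5e-3, 2.5e-3), function(h) {
    abs(grad_potential(Vquart, 1.3, h = h) - 4 * 1.3^3)
  }, numeric(1))
  order_est <- log2(err[1] / err[2])
  expect_lt(abs(order_est - 2), 0.5)
  suppressWarnings(
    expect_error(grad_potential(function(x) sqrt(x), -1e-10),
                 class = "cil_gradient_error"))
})

test_that("unadjusted Langevin attains the discrete stationary variance", {
  # AR(1) recursion: X <- (1-h)X + sqrt(2h) xi has variance 1/(1 - h/2)
  for (h in c(0.2, 0.1, 0.05)) {
    ens <- langevin_sample(gauss_potential,
                           matrix(rnorm(3000), ncol = 1),
                           h = h, n_steps = round(40 / h), seed = 71)
    v <- var(ens$positions[, 1])
    expect_lt(abs(v - 1 / (1 - h / 2)), 3 * sqrt(2 / 2999) * 1 / (1 - h / 2))
  }
  # zero-noise limit is gradient descent: the potential decreases monotonically
  x <- matrix(2.5)
  vals <- numeric(20)
  for (k in 1:20) {
    e <- langevin_sample(gauss_potential, x, h = 0.1, n_steps = 1, seed = k,
                         noise_scale = 0)
    x <- e$positions
    vals[k] <- gauss_potential(x[1, ])
  }
  expect_true(all(diff(vals) < 0))
  a <- langevin_sample(gauss_potential, matrix(1), h = 0.1, n_steps = 50,
                       seed = 5)
  b <- langevin_sample(gauss_potential, matrix(1), h = 0.1, n_steps = 50,
                       seed = 5)
  expect_identical(a$positions, b$positions)
})

test_that("a single SVGD particle performs scaled gradient descent", {
  one <- svgd_step(particle_ensemble(3), gauss_potential,
                   kernel_rbf(1), dt = 0.1)
  expect_equal(one$positions[1, 1], 3 - 0.1 * 1 * 3, tolerance = 1e-12)
  # coincident particles at the critical point form a fixed point
  flat <- particle_ensemble(matrix(0, 5, 1))
  stepped <- svgd_step(flat, gauss_potential, kernel_rbf(1), dt = 0.2)
  expect_equal(stepped$positions, flat$positions)
  expect_error(kernel_rbf(-1), class = "cil_validation_error")
})

test_that("a two-particle SVGD step matches direct evaluation of the dynamics", {
  ell <- 0.9
  X <- c(-0.5, 1.2)
  dt <- 0.05
  # direct arithmetic from the interacting-particle ODE with Gaussian kernel
  K <- function(r) exp(-r^2 / (2 * ell^2))
  dK <- function(r) -r / ell^2 * K(r)
  gV <- function(x) x
  expected <- vapply(1:2, function(i) {
    rep_term <- -mean(vapply(1:2, function(j) dK(X[i] - X[j]), numeric(1)))
    att_term <- -mean(vapply(1:2, function(j) K(X[i] - X[j]) * gV(X[j]),
                             numeric(1)))
    X[i] + dt * (rep_term + att_term)
  }, numeric(1))
  got <- svgd_step(particle_ensemble(X), gauss_potential, kernel_rbf(ell),
                   dt = dt)
  expect_equal(got$positions[, 1], expected, tolerance = 1e-12)
})

test_that("SVGD is deterministic and centres on the Gaussian target", {
  init <- matrix(seq(-3, 5, length.out = 100), ncol = 1)
  a <- svgd_sample(gauss_potential, init, dt = 0.2, n_steps = 300)
  b <- svgd_sample(gauss_potential, init, dt = 0.2, n_steps = 300)
  expect_identical(a$positions, b$positions)
  expect_lt(abs(mean(a$positions)), 0.05)
  # a kernel-density KL estimate against the target shrinks over the run
  grid <- seq(-8, 8, length.out = 401)
  target <- exp(-grid^2 / 2)
  target <- target / trapz_test(grid, target)
  kl_of <- function(pos) {
    de <- stats::density(pos, from = -8, to = 8, n = 401)
    kl_divergence_grids(de$y / trapz_test(grid, de$y), target, nodes = grid)
  }
  expect_lt(kl_of(a$positions[, 1]), kl_of(init[, 1]))
})
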