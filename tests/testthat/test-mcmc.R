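test_that("Metropolis accepts everything on a flat target and is reproducible", {
  ch <- metropolis(function(th) 0, c(0, 0), step_s = 1, n_steps = 500,
                   seed = 1)
  expect_equal(mean(ch$accepted), 1)
  a <- metropolis(function(th) -0.5 * sum(th^2), c(0), 0.5, 2000, seed = 3)
  b <- metropolis(function(th) -0.5 * sum(th^2), c(0), 0.5, 2000, seed = 3)
  expect_identical(a$samples, b$samples)
  # rejected proposals repeat the previous state
  rej <- which(!a$accepted)
  rej <- rej[rej > 1]
  expect_true(all(a$samples[rej, ] == a$samples[rej - 1, ]))
  expect_error(metropolis(function(th) -Inf, c(0), 1, 100, seed = 1),
               class = "cil_validation_error")
})

test_that("Metropolis recovers the moments of a 1-D standard normal", {
  ch <- metropolis(function(th) -0.5 * th^2, c(0), step_s = 5,
                   n_steps = 5e4, seed = 11)
  x <- ch$samples[10001:5e4, 1]
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(var(x) - 1), 0.1)
})

test_that("Hastings correction reduces to Metropolis for symmetric proposals", {
  lt <- function(th) -0.5 * sum(th^2)
  s <- 0.8
  prop <- list(
    sample = function(cur) cur + sqrt(s) * rnorm(length(cur)),
    log_density = function(from, to) -sum((to - from)^2) / (2 * s))
  mh <- metropolis_hastings(lt, prop, c(0.5), n_steps = 3000, seed = 21)
  m <- metropolis(lt, c(0.5), step_s = s, n_steps = 3000, seed = 21)
  expect_identical(mh$samples, m$samples)
  expect_identical(mh$accepted, m$accepted)
})

test_that("an independence proposal equal to the target always accepts", {
  prop <- list(sample = function(cur) rnorm(1),
               log_density = function(from, to) -0.5 * to^2)
  ch <- metropolis_hastings(function(th) -0.5 * th^2, prop, c(0),
                            n_steps = 2000, seed = 31)
  expect_equal(mean(ch$accepted), 1)
  # asymmetric random-walk proposal still targets the right moments
  shift <- 0.3
  prop2 <- list(
    sample = function(cur) cur + shift + rnorm(1),
    log_density = function(from, to) -0.5 * (to - from - shift)^2)
  ch2 <- metropolis_hastings(function(th) -0.5 * th^2, prop2, c(0),
                             n_steps = 4e4, seed = 32)
  x <- ch2$samples[8001:4e4, 1]
  expect_lt(abs(mean(x)), 0.06)
  expect_lt(abs(var(x) - 1), 0.12)
})

test_that("adaptive Metropolis reduces to plain Metropolis when disabled", {
  lt <- function(th) -0.5 * sum(th^2)
  am <- adaptive_metropolis(lt, c(1, -1), n_steps = 1500,
                            adapt_cfg = list(t0 = 1500, C0 = diag(0.7, 2)),
                            seed = 13)
  m <- metropolis(lt, c(1, -1), step_s = 0.7, n_steps = 1500, seed = 13)
  expect_identical(am$samples, m$samples)
})

test_that("the recursive covariance equals a batch recomputation", {
  lt <- function(th) -0.5 * sum(th^2)
  am <- adaptive_metropolis(lt, c(0.2, -0.4), n_steps = 900,
                            adapt_cfg = list(t0 = 100), seed = 17)
  # moments were updated with theta0 and the first n-1 realised states
  hist <- rbind(c(0.2, -0.4), am$samples[1:(nrow(am$samples) - 1), ])
  expect_equal(am$proposal_cfg$cov_history, cov(hist), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("adaptation learns an anisotropic target scale", {
  lt <- function(th) -0.5 * (th[1]^2 + th[2]^2 / 100)
  am <- adaptive_metropolis(lt, c(0, 0), n_steps = 3e4,
                            adapt_cfg = list(t0 = 500), seed = 19)
  d <- chain_diagnostics(am)
  ratio <- d$cov[2, 2] / d$cov[1, 1]
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
  expect_gt(d$acceptance_rate, 0.1)
})

test_that("empirical transition flows satisfy detailed balance", {
  # stationary Metropolis chain on a standard normal, coarse 3-state binning:
  # detailed balance makes the i->j and j->i flow counts match
  ch <- metropolis(function(th) -0.5 * th^2, c(0), step_s = 1.5,
                   n_steps = 1e5, seed = 23)
  x <- ch$samples[, 1]
  states <- cut(x, breaks = c(-Inf, -0.43, 0.43, Inf), labels = FALSE)
  from <- states[-length(states)]
  to <- states[-1]
  for (i in 1:2) for (j in (i + 1):3) {
    nij <- sum(from == i & to == j)
    nji <- sum(from == j & to == i)
    expect_lt(abs(nij - nji), 3 * sqrt(nij + nji))
  }
})

test_that("chain diagnostics report ESS, burn-in and acceptance", {
  iid <- new_chain_test(matrix(rnorm(4000), ncol = 2))
  d <- chain_diagnostics(iid, burn_in_fraction = 0)
  expect_true(all(abs(d$ess - 2000) / 2000 < 0.1))
  expect_equal(d$acceptance_rate, 1)
  const <- new_chain_test(matrix(1, 100, 1), accepted = rep(FALSE, 100))
  dc <- chain_diagnostics(const, burn_in_fraction = 0.3)
  expect_true(dc$degenerate[1])
  expect_equal(dc$ess[[1]], 1)
  expect_equal(dc$acceptance_rate, 0)
  expect_error(chain_diagnostics(iid, burn_in_fraction = 1),
               class = "cil_validation_error")
})
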