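# Shared fixtures: small model configurations kept fast enough for unit
# tests; the acceptance tests use the full study conditions.

quick_turing_grid <- list(nx = 48, length = 30)
quick_turing_solver <- list(max_time = 250, dt = 0.1)

make_turing_model <- function(grid = quick_turing_grid,
                              solver_cfg = quick_turing_solver,
                              ic_amplitude = 0.01) {
  cil_model(function(theta, n, seed) {
    simulate_turing_ensemble(n, theta = theta, grid = grid,
                             ic_amplitude = ic_amplitude, seed = seed,
                             solver_cfg = solver_cfg)
  }, kind = "pattern", name = "turing-test")
}

make_lorenz_model <- function(epsilon = 1e-2, dt_sample = 0.25,
                              t_transient = 3) {
  cil_model(function(theta, n, seed) {
    x0 <- perturb_initial_state(chaotic_system("lorenz63")$default_x0,
                                epsilon, seed)
    times <- c(0, t_transient + dt_sample * (0:(n - 1)))
    ts <- simulate_chaotic(theta, x0, times)
    trajectory_set(ts$times[-1], ts$states[-1, , drop = FALSE])
  }, kind = "trajectory", name = "lorenz-test")
}

colony_theta_star <- c(alpha = 0.3, sigma_k = 0.15, sigma_s = 0.25,
                       sigma_o = 0.05)

# standard-normal potential with analytic gradient
gauss_potential <- local({
  V <- function(x) 0.5 * sum(x^2)
  attr(V, "gradient") <- function(x) x
  V
})

`%||%` <- function(a, b) if (is.null(a)) b else a

trapz_test <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# wrap a sample matrix as an mcmc_chain for diagnostics tests
new_chain_test <- function(samples, accepted = rep(TRUE, nrow(samples))) {
  structure(list(samples = samples, log_target = rep(0, nrow(samples)),
                 accepted = accepted, proposal_cfg = list(), seed = 0L),
            class = "mcmc_chain")
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# hand-rolled quadratic-form oracle for Mahalanobis-type checks
dense_quadform <- function(r, S) drop(t(r) %*% solve(S) %*% r)

# build a cil_statistics object directly (bypassing estimation) for
# cost-evaluation unit tests
manual_stats <- function(mu, sigma, bins) {
  structure(list(mu = mu, sigma = sigma, chol = chol(sigma), bins = bins,
                 n_realisations = length(mu) * 10, regularisation = 0,
                 kind = "pattern", metric = "L2", norm = "L2",
                 N = 2, components = NULL, subsets = NULL,
                 realisations = NULL),
            class = "cil_statistics")
}
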