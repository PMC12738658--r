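## Turing pattern simulator: Schnakenberg reaction-diffusion system solved by
## a semi-implicit (IMEX) finite-difference scheme with no-flux boundaries.
## The compiled stepper lives in src/rd_integrate.cpp.

#' Default Schnakenberg model parameters
#'
#' Kinetics \eqn{u_t = D_u \Delta u + \gamma(a - u + u^2 v)},
#' \eqn{v_t = D_v \Delta v + \gamma(b - u^2 v)}. The defaults
#' (`a = 0.1`, `b = 0.9`, `gamma = 1`, `Du = 1`, `Dv = 40`) lie inside the
#' Turing instability region: the homogeneous steady state
#' \eqn{u^* = a + b}, \eqn{v^* = b/(a+b)^2} is stable to homogeneous
#' perturbations but unstable to a band of spatial wavenumbers.
#'
#' @return Named numeric vector of model parameters.
#' @export
schnakenberg_params <- function() {
  c(a = 0.1, b = 0.9, gamma = 1, Du = 1, Dv = 40)
}

#' @rdname schnakenberg_params
#' @param theta named parameters (`a`, `b`, `gamma`, `Du`, `Dv`).
#' @return `schnakenberg_steady()`: the homogeneous steady state `c(u, v)`.
#' @export
schnakenberg_steady <- function(theta = schnakenberg_params()) {
  u <- theta[["a"]] + theta[["b"]]
  c(u = u, v = theta[["b"]] / u^2)
}

#' Linear growth rate of spatial modes (dispersion relation)
#'
#' Largest real part of the eigenvalues of \eqn{J - k^2 D} where `J` is the
#' reaction Jacobian at the homogeneous steady state and `D = diag(Du, Dv)`.
#' Positive values indicate Turing-unstable wavenumbers.
#'
#' @param k2 numeric vector of squared wavenumbers.
#' @param theta Schnakenberg parameters.
#' @return Numeric vector of growth rates, one per element of `k2`.
#' @export
turing_growth_rate <- function(k2, theta = schnakenberg_params()) {
  ss <- schnakenberg_steady(theta)
  g <- theta[["gamma"]]
  fu <- g * (-1 + 2 * ss[["u"]] * ss[["v"]])
  fv <- g * ss[["u"]]^2
  gu <- g * (-2 * ss[["u"]] * ss[["v"]])
  gv <- g * (-ss[["u"]]^2)
  vapply(k2, function(kk) {
    tr <- (fu - theta[["Du"]] * kk) + (gv - theta[["Dv"]] * kk)
    det <- (fu - theta[["Du"]] * kk) * (gv - theta[["Dv"]] * kk) - fv * gu
    disc <- tr^2 - 4 * det
    if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
  }, numeric(1))
}

#' @rdname turing_growth_rate
#' @param L domain length; admissible no-flux wavenumbers are
#'   \eqn{k_m = m\pi/L}.
#' @param max_mode highest mode index searched.
#' @return `turing_fastest_mode()`: the mode index m maximising the growth
#'   rate, with the rate attached as attribute `"rate"`.
#' @export
turing_fastest_mode <- function(theta = schnakenberg_params(), L,
                                max_mode = 32) {
  m <- seq_len(max_mode)
  lam <- turing_growth_rate((m * pi / L)^2, theta)
  best <- which.max(lam)
  structure(best, rate = lam[best])
}

#' Simulate one Turing pattern
#'
#' Integrates the Schnakenberg system from the homogeneous steady state plus
#' seeded Gaussian noise of size `ic_amplitude`, until the max-norm relative
#' change per unit time falls below the stationarity tolerance or `max_time`
#' is reached. Diffusion is treated implicitly (dimensional splitting in 2-D)
#' and reaction explicitly, so the scheme is stable for reaction-limited time
#' steps.
#'
#' @param theta Schnakenberg parameters; see [schnakenberg_params()].
#' @param grid list with `nx` (cells), optional `ny` (default 1 = 1-D) and
#'   `length` (physical domain length in x, default 40).
#' @param ic_amplitude standard deviation of the initial perturbation; 0
#'   reproduces the homogeneous steady state exactly (up to round-off).
#' @param seed integer seed for the initial noise.
#' @param solver_cfg list: `dt` (0.1), `max_time` (400), `check_every` (50
#'   steps), `stationarity_tol` (1e-6 relative change per unit time).
#' @param component which field to return: `"u"` (default) or `"v"`.
#' @param normalise if `TRUE` the returned pattern is shifted/scaled to zero
#'   mean and unit standard deviation (emulating data known only up to scale).
#' @return A [pattern_ensemble()] holding one pattern, with attributes
#'   `stationary` (logical), `time` (integration time reached) and `seed`.
#' @export
#' @examples
#' p <- simulate_turing(seed = 1, grid = list(nx = 32, length = 20),
#'                      solver_cfg = list(max_time = 50))
simulate_turing <- function(theta = schnakenberg_params(),
                            grid = list(nx = 64, length = 40),
                            ic_amplitude = 0.01, seed = 1,
                            solver_cfg = list(), component = "u",
                            normalise = FALSE) {
  theta <- param_values(theta)
  if (theta[["Du"]] <= 0 || theta[["Dv"]] <= 0) {
    stop_cil("diffusion coefficients must be positive", "cil_validation_error")
  }
  cfg <- modifyList(list(dt = 0.1, max_time = 400, check_every = 50,
                         stationarity_tol = 1e-6), solver_cfg)
  nx <- as.integer(grid$nx %||% 64)
  ny <- as.integer(grid$ny %||% 1)
  L <- grid$length %||% 40
  hx <- L / nx
  ss <- schnakenberg_steady(theta)
  ntot <- nx * ny
  noise <- if (ic_amplitude > 0) {
    with_seed_(seed, matrix(rnorm(2 * ntot), ncol = 2))
  } else matrix(0, ntot, 2)
  u0 <- ss[["u"]] + ic_amplitude * noise[, 1]
  v0 <- ss[["v"]] + ic_amplitude * noise[, 2]
  res <- rd_integrate_cpp(u0, v0, nx, ny,
                          theta[["a"]], theta[["b"]], theta[["gamma"]],
                          theta[["Du"]], theta[["Dv"]], hx, cfg$dt,
                          max_steps = as.integer(ceiling(cfg$max_time / cfg$dt)),
                          check_every = as.integer(cfg$check_every),
                          stat_tol = cfg$stationarity_tol)
  if (res$diverged) {
    stop_cil(sprintf("Turing simulation diverged near t = %g",
                     res$divergence_time), "cil_divergence_error")
  }
  pat <- if (component == "v") res$v else res$u
  if (ny > 1) pat <- matrix(pat, nrow = nx, ncol = ny)
  if (normalise) {
    s <- sd(pat)
    pat <- if (s > 0) (pat - mean(pat)) / s else pat - mean(pat)
  }
  ens <- pattern_ensemble(list(pat), component_mask = component,
                          normalised = normalise)
  attr(ens, "stationary") <- res$stationary
  attr(ens, "time") <- res$time
  attr(ens, "seed") <- seed
  ens
}

#' Simulate an ensemble of independent Turing patterns
#'
#' Repeated calls to [simulate_turing()] with independent seeds derived from
#' `seed`; the resulting patterns are i.i.d. realisations of the pattern
#' distribution at `theta`.
#'
#' @inheritParams simulate_turing
#' @param n number of patterns.
#' @return A [pattern_ensemble()] with `n` patterns.
#' @export
simulate_turing_ensemble <- function(n, theta = schnakenberg_params(),
                                     grid = list(nx = 64, length = 40),
                                     ic_amplitude = 0.01, seed = 1,
                                     solver_cfg = list(), component = "u",
                                     normalise = FALSE) {
  pats <- vector("list", n)
  stat <- logical(n)
  for (i in seq_len(n)) {
    one <- simulate_turing(theta, grid, ic_amplitude,
                           seed = derive_seed(seed, i), solver_cfg = solver_cfg,
                           component = component, normalise = normalise)
    pats[[i]] <- one$patterns[[1]]
    stat[i] <- attr(one, "stationary")
  }
  ens <- pattern_ensemble(pats, component_mask = component,
                          normalised = normalise)
  attr(ens, "stationary") <- stat
  attr(ens, "seed") <- seed
  ens
}
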