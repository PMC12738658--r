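## Nonlocal logistic colony growth model, radially reduced.
##
## The volumetric density n(x, t) obeys  dn/dt = alpha (k * n)(1 - n)  with a
## normalised ball-indicator kernel of radius sigma_k. For radially symmetric
## k and n the 3-D convolution collapses to a 1-D integral
##   (k * n)(r) = (2 pi / r) int_0^inf s n(s) [ int_{|r-s|}^{r+s} t K(t) dt ] ds,
## which is precomputed as a dense kernel matrix on the radial grid. The
## observable radial density is p(r, t) = 4 pi r^2 n(r, t).

#' Radial kernel matrix of the ball-indicator convolution
#'
#' Matrix `W` such that `(k * n)(r_i) = sum_j W[i, j] n(s_j)` by the midpoint
#' rule on a cell-centred radial grid, for the normalised kernel
#' \eqn{K(t) = 3/(4\pi\sigma_k^3)} on \eqn{[0, \sigma_k]} (unit 3-D integral).
#'
#' @param r cell-centred radial grid (uniform spacing).
#' @param sigma_k kernel radius, > 0.
#' @return Dense `length(r) x length(r)` matrix.
#' @export
colony_kernel_matrix <- function(r, sigma_k) {
  stopifnot(sigma_k > 0)
  h <- r[2] - r[1]
  a <- pmin(abs(outer(r, r, "-")), sigma_k)
  b <- pmin(outer(r, r, "+"), sigma_k)
  # inner integral of t*K(t) over [a, b], times 2 pi s / r, times cell width
  W <- (3 / (4 * sigma_k^3)) * outer(1 / r, r) * (b^2 - a^2) * h
  W
}

#' Simulate the nonlocal colony growth model
#'
#' Solves the radially reduced nonlocal logistic equation on `[0, r_max]` by
#' the method of lines with an adaptive ODE integrator. The initial colony is
#' the indicator of a ball of radius `sigma_s` (the boundary cell holds its
#' covered fraction, so the discrete initial mass matches the continuum value
#' to second order).
#'
#' @param theta named parameters `alpha` (proliferation rate, 1/time),
#'   `sigma_k` (kernel radius) and `sigma_s` (initial colony radius), all
#'   positive (`alpha = 0` is allowed and freezes the density).
#' @param r_max domain radius; must exceed the expected colony growth.
#' @param n_r number of radial cells.
#' @param t_grid output times (must start at 0; 0 is prepended otherwise).
#' @param solver_cfg list: `method` ("lsoda"), `rtol` (1e-6), `atol` (1e-9),
#'   `overflow_tol` (1e-4): maximum tolerated density in the outermost cell.
#' @return An object of class `colony_solution`: list with `r_grid`,
#'   `t_grid`, volumetric density matrix `n` (cells x times) and radial
#'   density `p = 4 pi r^2 n`. Attribute `clamp_excess` reports by how much
#'   `n` left `[0, 1]` (solver tolerance scale).
#' @export
#' @examples
#' sol <- simulate_colony(c(alpha = 0.3, sigma_k = 0.15, sigma_s = 0.25),
#'                        t_grid = c(0, 5, 10))
#' colony_radius(sol, t_index = 3)
simulate_colony <- function(theta, r_max = 3, n_r = 120,
                            t_grid = seq(0, 20, by = 2),
                            solver_cfg = list()) {
  theta <- param_values(theta)
  alpha <- theta[["alpha"]]; sigma_k <- theta[["sigma_k"]]
  sigma_s <- theta[["sigma_s"]]
  if (alpha < 0 || sigma_k <= 0 || sigma_s <= 0) {
    stop_cil("colony parameters must satisfy alpha >= 0, sigma_k > 0, sigma_s > 0",
             "cil_validation_error")
  }
  if (sigma_s >= r_max) {
    stop_cil("r_max must exceed the initial colony radius", "cil_domain_error")
  }
  cfg <- modifyList(list(method = "lsoda", rtol = 1e-6, atol = 1e-9,
                         overflow_tol = 1e-4), solver_cfg)
  if (t_grid[1] > 0) t_grid <- c(0, t_grid)
  h <- r_max / n_r
  r <- (seq_len(n_r) - 0.5) * h
  # covered fraction of each cell by the ball of radius sigma_s
  n0 <- pmin(pmax((sigma_s - (r - h / 2)) / h, 0), 1)
  W <- colony_kernel_matrix(r, sigma_k)
  rhs <- function(t, n, parms) {
    list(alpha * (W %*% n) * (1 - n))
  }
  out <- if (alpha == 0 || length(t_grid) == 1L) {
    matrix(n0, nrow = n_r, ncol = length(t_grid))
  } else {
    sol <- deSolve::ode(y = n0, times = t_grid, func = rhs, parms = NULL,
                        method = cfg$method, rtol = cfg$rtol, atol = cfg$atol)
    t(unname(as.matrix(sol[, -1, drop = FALSE])))
  }
  if (!all(is.finite(out))) {
    stop_cil("colony solver produced non-finite densities",
             "cil_divergence_error")
  }
  clamp_excess <- max(0, max(out) - 1, -min(out))
  out <- pmin(pmax(out, 0), 1)
  if (max(out[n_r, ]) > cfg$overflow_tol) {
    stop_cil(sprintf(
      "colony mass reached the domain boundary (n(r_max) = %.3g); increase r_max",
      max(out[n_r, ])), "cil_domain_error")
  }
  p <- 4 * pi * r^2 * out
  structure(list(r_grid = r, t_grid = t_grid, n = out, p = p),
            class = "colony_solution", clamp_excess = clamp_excess)
}

#' @export
print.colony_solution <- function(x, ...) {
  cat(sprintf("<colony_solution> %d radial cells on [0, %g], %d times in [%g, %g]\n",
              length(x$r_grid), max(x$r_grid) + diff(x$r_grid[1:2]) / 2,
              length(x$t_grid), min(x$t_grid), max(x$t_grid)))
  invisible(x)
}

#' Colony radius enclosing a mass fraction
#'
#' The radius \eqn{r_\theta(t)} is the smallest `q` whose enclosed mass
#' \eqn{\int_0^q p\,dr} exceeds `mass_fraction` of the total mass. Cumulative
#' mass is computed by trapezoidal quadrature (with the exact `p(0) = 0`
#' endpoint) and inverted by linear interpolation between grid nodes.
#'
#' @param sol a `colony_solution`.
#' @param t_index column index into `sol$t_grid`.
#' @param mass_fraction fraction of total mass enclosed, default 0.95.
#' @return The radius (same length units as the grid).
#' @export
colony_radius <- function(sol, t_index, mass_fraction = 0.95) {
  stopifnot(inherits(sol, "colony_solution"))
  if (t_index < 1 || t_index > length(sol$t_grid)) {
    stop_cil("t_index out of range", "cil_validation_error")
  }
  r <- c(0, sol$r_grid)
  p <- c(0, sol$p[, t_index])
  cum <- cumtrapz_(r, p)
  total <- cum[length(cum)]
  if (total <= 0) {
    stop_cil("colony radius undefined: zero total mass", "cil_validation_error")
  }
  target <- mass_fraction * total
  i <- which(cum > target)[1]
  if (is.na(i)) return(r[length(r)])
  if (i == 1L) return(0)
  r[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) * (r[i] - r[i - 1])
}

#' Colony radii along a time grid
#'
#' Convenience wrapper: simulate the colony model at `theta` and return the
#' 95%-mass radius at each requested time.
#'
#' @inheritParams simulate_colony
#' @param times observation times (0 allowed).
#' @param mass_fraction see [colony_radius()].
#' @return Numeric vector of radii, one per element of `times`.
#' @export
colony_forward_radii <- function(theta, times, r_max = 3, n_r = 120,
                                 mass_fraction = 0.95, solver_cfg = list()) {
  tu <- sort(unique(times)) # the solver needs increasing times; map back below
  sol <- simulate_colony(theta, r_max = r_max, n_r = n_r, t_grid = tu,
                         solver_cfg = solver_cfg)
  idx <- match(times, sol$t_grid)
  vapply(idx, function(i) colony_radius(sol, i, mass_fraction), numeric(1))
}

#' Observe radii under multiplicative lognormal noise
#'
#' Applies the multiplicative error model
#' \eqn{r_o^i = r(t_i)\,\exp(\tilde Z_i)}, \eqn{\tilde Z_i \sim N(0, \sigma_o^2)},
#' i.e. additive Gaussian noise of standard deviation `sigma_o` on the log
#' scale. Observed radii are therefore strictly positive.
#'
#' @param true_radii positive numeric vector of true radii.
#' @param sigma_o noise standard deviation on the log scale, >= 0.
#' @param seed integer seed.
#' @param times observation times (stored alongside; defaults to an index).
#' @return A `radius_measurements` data frame with columns `time`, `r_true`,
#'   `r_obs`.
#' @export
observe_radius <- function(true_radii, sigma_o, seed,
                           times = seq_along(true_radii)) {
  stopifnot(all(true_radii > 0), sigma_o >= 0,
            length(times) == length(true_radii))
  z <- if (sigma_o > 0) {
    with_seed_(seed, rnorm(length(true_radii), sd = sigma_o))
  } else rep(0, length(true_radii))
  out <- data.frame(time = times, r_true = true_radii,
                    r_obs = true_radii * exp(z))
  class(out) <- c("radius_measurements", "data.frame")
  out
}
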