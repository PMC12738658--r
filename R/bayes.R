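## Classical Gaussian Bayesian building blocks: prior, likelihood, potential.

#' Gaussian prior
#'
#' @param m prior mean vector.
#' @param Sigma_prior symmetric positive-definite covariance matrix.
#' @return An object of class `gaussian_prior` with a cached Cholesky factor.
#' @export
gaussian_prior <- function(m, Sigma_prior) {
  Sigma_prior <- as.matrix(Sigma_prior)
  if (!isTRUE(all.equal(Sigma_prior, t(Sigma_prior)))) {
    stop_cil("prior covariance must be symmetric", "cil_validation_error")
  }
  R <- tryCatch(chol(Sigma_prior), error = function(e) {
    stop_cil("prior covariance must be positive definite",
             "cil_validation_error")
  })
  structure(list(m = as.numeric(m), Sigma = Sigma_prior, chol = R),
            class = "gaussian_prior")
}

#' Unnormalised Gaussian log-prior
#'
#' \eqn{-\tfrac12 (\theta - m)^\top \Sigma^{-1} (\theta - m)}.
#'
#' @param theta parameter vector.
#' @param prior a [gaussian_prior()].
#' @return Scalar log-density (unnormalised, always <= 0).
#' @export
log_prior <- function(theta, prior) {
  stopifnot(inherits(prior, "gaussian_prior"))
  theta <- if (inherits(theta, "parameter_vector")) theta$values else theta
  if (length(theta) != length(prior$m)) {
    stop_cil("theta and prior dimensions differ", "cil_validation_error")
  }
  z <- forwardsolve(t(prior$chol), theta - prior$m)
  -0.5 * sum(z^2)
}

#' Unnormalised Gaussian log-likelihood
#'
#' \eqn{-\tfrac12 (D - \mathcal{M}(\theta))^\top \Gamma^{-1} (D - \mathcal{M}(\theta))}
#' for data `D`, model prediction and noise covariance `Gamma`.
#'
#' @param D data vector.
#' @param prediction model prediction, same length as `D`.
#' @param Gamma noise covariance (matrix, or scalar/vector taken as diagonal).
#' @return Scalar log-likelihood (unnormalised).
#' @export
gaussian_loglik <- function(D, prediction, Gamma) {
  if (length(D) != length(prediction)) {
    stop_cil("data and prediction dimensions differ", "cil_validation_error")
  }
  r <- D - prediction
  if (is.matrix(Gamma)) {
    z <- forwardsolve(t(chol(Gamma)), r)
    return(-0.5 * sum(z^2))
  }
  -0.5 * sum(r^2 / rep_len(Gamma, length(r)))
}

#' Posterior potential specification
#'
#' The potential \eqn{V(\theta) = \tfrac12 |D - \mathcal{M}(\theta)|^2_\Gamma
#' + \tfrac12 |\theta - m|^2_\Sigma} whose Boltzmann density
#' \eqn{e^{-V(\theta)}} is the (unnormalised) posterior.
#'
#' @param forward_map function `theta -> prediction vector`.
#' @param D data vector.
#' @param Gamma noise covariance (matrix or diagonal).
#' @param prior a [gaussian_prior()].
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(forward_map, D, Gamma, prior) {
  stopifnot(is.function(forward_map), inherits(prior, "gaussian_prior"))
  structure(list(forward_map = forward_map, D = D, Gamma = Gamma,
                 prior = prior), class = "potential_spec")
}

#' Evaluate the posterior potential
#'
#' Forward-model failures are mapped to an infinite potential (zero posterior
#' mass) with a warning rather than an error, so that samplers survive
#' proposals in non-physical parameter regions.
#'
#' @param theta parameter vector.
#' @param spec a [potential_spec()].
#' @return Non-negative scalar; `Inf` on forward-model failure.
#' @export
potential <- function(theta, spec) {
  stopifnot(inherits(spec, "potential_spec"))
  pred <- tryCatch(spec$forward_map(theta), error = function(e) {
    warning(sprintf("forward model failed (%s): potential set to Inf",
                    conditionMessage(e)))
    NULL
  })
  if (is.null(pred) || !all(is.finite(pred))) return(Inf)
  -gaussian_loglik(spec$D, pred, spec$Gamma) - log_prior(theta, spec$prior)
}

#' Log-likelihood of radius measurements under the colony model
#'
#' Lognormal multiplicative-error likelihood
#' \deqn{\sum_i \left[-\log(\sqrt{2\pi}\,\sigma_o)
#'   - (\log r_o^i - \log r_\theta(t_i))^2 / (2\sigma_o^2)\right],}
#' where \eqn{r_\theta(t_i)} is the 95%-mass radius of the simulated colony.
#' The \eqn{\sigma_o}-dependent normalising term is kept because
#' \eqn{\sigma_o} is itself estimated.
#'
#' @param meas a `radius_measurements` data frame (see [observe_radius()]).
#' @param theta named parameters `alpha`, `sigma_k`, `sigma_s`, `sigma_o` on
#'   the natural scale, or a [parameter_vector()] carrying logs.
#' @param r_max,n_r,solver_cfg forwarded to [simulate_colony()].
#' @return Scalar log-likelihood; `-Inf` (with a warning) on solver failure.
#' @export
colony_loglik <- function(meas, theta, r_max = 3, n_r = 120,
                          solver_cfg = list()) {
  theta <- param_values(theta)
  sigma_o <- theta[["sigma_o"]]
  if (sigma_o <= 0) {
    stop_cil("sigma_o must be positive", "cil_validation_error")
  }
  r_theta <- tryCatch(
    colony_forward_radii(theta[c("alpha", "sigma_k", "sigma_s")], meas$time,
                         r_max = r_max, n_r = n_r, solver_cfg = solver_cfg),
    error = function(e) {
      warning(sprintf("colony solver failed (%s): loglik set to -Inf",
                      conditionMessage(e)))
      NULL
    })
  if (is.null(r_theta) || any(!is.finite(r_theta)) || any(r_theta <= 0)) {
    return(-Inf)
  }
  resid <- log(meas$r_obs) - log(r_theta)
  sum(-log(sqrt(2 * pi) * sigma_o) - resid^2 / (2 * sigma_o^2))
}

#' Plain Monte Carlo integration on the unit cube
#'
#' \eqn{\int_{[0,1]^d} f \approx n^{-1} \sum_i f(X_i)} with `X_i` uniform on
#' the cube.
#'
#' @param f scalar function of a length-`d` numeric vector.
#' @param n number of samples.
#' @param seed integer seed.
#' @param d dimension of the cube (default 1).
#' @return Scalar estimate.
#' @export
mc_integrate <- function(f, n, seed, d = 1) {
  stopifnot(n >= 1)
  X <- with_seed_(seed, matrix(runif(n * d), nrow = n, ncol = d))
  vals <- apply(X, 1L, f)
  bad <- which(!is.finite(vals))
  if (length(bad) > 0) {
    stop_cil(sprintf("non-finite integrand value at sample point (%s)",
                     paste(signif(X[bad[1], ], 4), collapse = ", ")),
             "cil_numerical_error")
  }
  mean(vals)
}
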