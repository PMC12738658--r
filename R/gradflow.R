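## Gradient-flow samplers: potential gradients, unadjusted Langevin,
## Stein variational gradient descent.

#' Gradient of a potential
#'
#' Uses an analytic gradient when one is attached to `V` (attribute
#' `"gradient"`, a function of theta), otherwise central finite differences
#' with a relative step.
#'
#' @param V potential function `theta -> scalar`.
#' @param theta evaluation point.
#' @param h relative finite-difference step (default 1e-5).
#' @return Numeric gradient vector.
#' @export
#' @examples
#' grad_potential(function(x) 0.5 * sum(x^2), c(1, -2))
grad_potential <- function(V, theta, h = 1e-5) {
  g_fn <- attr(V, "gradient")
  if (is.function(g_fn)) return(g_fn(theta))
  d <- length(theta)
  g <- numeric(d)
  for (i in seq_len(d)) {
    hi <- h * (1 + abs(theta[i]))
    up <- theta; up[i] <- up[i] + hi
    dn <- theta; dn[i] <- dn[i] - hi
    vu <- V(up); vd <- V(dn)
    if (!is.finite(vu) || !is.finite(vd)) {
      stop_cil(sprintf("non-finite potential in gradient stencil at component %d", i),
               "cil_gradient_error")
    }
    g[i] <- (vu - vd) / (2 * hi)
  }
  g
}

#' Particle ensemble
#'
#' Uniformly weighted particle positions, as evolved by the Langevin and
#' SVGD dynamics.
#'
#' @param positions N x d numeric matrix (a vector is treated as N x 1).
#' @param time time stamp of the ensemble.
#' @return An object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(positions, time = 0) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1)
  check_finite(positions, "particle positions")
  structure(list(positions = positions, weights = rep(1 / nrow(positions),
                                                      nrow(positions)),
                 time = time),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> N = %d particles, d = %d, t = %g\n",
              nrow(x$positions), ncol(x$positions), x$time))
  invisible(x)
}

#' Unadjusted Langevin sampling (Euler-Maruyama)
#'
#' Discretises the overdamped Langevin diffusion
#' \eqn{dX = -\nabla V(X)\,dt + \sqrt{2}\,dB} as
#' \eqn{X_{k+1} = X_k - h\nabla V(X_k) + \sqrt{2h}\,\xi_k}, independently per
#' particle. For \eqn{V = \theta^2/2} in 1-D the chain is an AR(1) process
#' with stationary variance \eqn{1/(1 - h/2)}, which tends to the exact value
#' 1 as \eqn{h \to 0}.
#'
#' @param V potential function (analytic gradient used if attached; see
#'   [grad_potential()]).
#' @param theta0_ensemble initial positions: a [particle_ensemble()], matrix
#'   or vector.
#' @param h time step, > 0.
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param noise_scale multiplier on the Brownian term (default 1; 0 turns the
#'   scheme into plain gradient descent).
#' @param store_every if > 0, the trajectory is recorded every that many
#'   steps (attribute `"trajectory"` of the result).
#' @return The final [particle_ensemble()]; particles that left the finite
#'   range are reported in attribute `"diverged"`.
#' @export
langevin_sample <- function(V, theta0_ensemble, h, n_steps, seed,
                            noise_scale = 1, store_every = 0) {
  stopifnot(h > 0)
  ens <- if (inherits(theta0_ensemble, "particle_ensemble")) {
    theta0_ensemble
  } else particle_ensemble(theta0_ensemble)
  X <- ens$positions
  N <- nrow(X); d <- ncol(X)
  traj <- list()
  with_seed_(seed, {
    for (k in seq_len(n_steps)) {
      G <- t(apply(X, 1L, function(x) grad_potential(V, x)))
      if (d == 1L) G <- matrix(G, ncol = 1)
      X <- X - h * G +
        noise_scale * sqrt(2 * h) * matrix(rnorm(N * d), N, d)
      if (store_every > 0 && k %% store_every == 0) {
        traj[[length(traj) + 1L]] <- particle_ensemble(
          X[is.finite(rowSums(X)), , drop = FALSE], time = k * h)
      }
    }
  })
  bad <- !is.finite(rowSums(X))
  out <- particle_ensemble(X[!bad, , drop = FALSE],
                           time = ens$time + n_steps * h)
  attr(out, "diverged") <- which(bad)
  if (store_every > 0) attr(out, "trajectory") <- traj
  out
}

#' Gaussian RBF kernel specification
#'
#' Kernel \eqn{K(r) = \exp(-\|r\|^2 / (2\ell^2))} with bandwidth \eqn{\ell}
#' either fixed or set by the median heuristic
#' \eqn{\ell^2 = \mathrm{med}^2 / (2\log(N + 1))}, recomputed from the
#' current ensemble at every step.
#'
#' @param bandwidth positive numeric, or `"median"` (default).
#' @return An object of class `kernel_spec`.
#' @export
kernel_rbf <- function(bandwidth = "median") {
  if (is.numeric(bandwidth) && bandwidth <= 0) {
    stop_cil("kernel bandwidth must be positive", "cil_validation_error")
  }
  structure(list(family = "rbf", bandwidth = bandwidth),
            class = "kernel_spec")
}

kernel_bandwidth_ <- function(kernel, X) {
  if (is.numeric(kernel$bandwidth)) return(kernel$bandwidth)
  N <- nrow(X)
  if (N == 1L) return(1)
  d2 <- as.vector(dist(X))^2
  med2 <- median(d2)
  if (med2 <= 0) return(1)
  sqrt(med2 / (2 * log(N + 1)))
}

#' One explicit-Euler step of Stein variational gradient descent
#'
#' Advances the particle system
#' \deqn{\dot\theta_i = -\frac1N\sum_j \nabla K(\theta_i - \theta_j)
#'   - \frac1N\sum_j K(\theta_i - \theta_j)\,\nabla V(\theta_j)}
#' by one step of size `dt`. The first (kernel-gradient) term repels
#' particles from one another; the second is kernel-weighted gradient descent
#' on the potential. With a single particle and a symmetric kernel the update
#' reduces to scaled gradient descent
#' \eqn{\theta \leftarrow \theta - dt\,K(0)\nabla V(\theta)}.
#'
#' @param ensemble a [particle_ensemble()].
#' @param V potential function.
#' @param kernel a [kernel_rbf()] specification.
#' @param dt step size, > 0.
#' @return The updated [particle_ensemble()]; the maximum particle
#'   displacement is attached as attribute `"max_displacement"`.
#' @export
svgd_step <- function(ensemble, V, kernel = kernel_rbf(), dt) {
  stopifnot(dt > 0, inherits(ensemble, "particle_ensemble"))
  X <- ensemble$positions
  N <- nrow(X); d <- ncol(X)
  ell <- kernel_bandwidth_(kernel, X)
  G <- t(apply(X, 1L, function(x) grad_potential(V, x)))
  if (d == 1L) G <- matrix(G, ncol = 1)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  K <- exp(-pmax(d2, 0) / (2 * ell^2))
  # repulsion: -(1/N) sum_j grad K(x_i - x_j) = (1/N) sum_j K_ij (x_i-x_j)/ell^2
  drift_att <- -(K %*% G) / N
  drift_rep <- (X * rowSums(K) - K %*% X) / (N * ell^2)
  Xn <- X + dt * (drift_att + drift_rep)
  out <- particle_ensemble(Xn, time = ensemble$time + dt)
  attr(out, "max_displacement") <- max(abs(Xn - X))
  out
}

#' Run SVGD to (approximate) stationarity
#'
#' Iterates [svgd_step()] until the maximum particle displacement in one step
#' drops below `tol`, or `n_steps` is reached. The dynamics contain no
#' randomness: identical initial ensembles give identical results.
#'
#' @inheritParams svgd_step
#' @param init_ensemble initial [particle_ensemble()] (or matrix / vector).
#' @param n_steps maximum number of steps.
#' @param tol convergence threshold on the per-step max displacement.
#' @param monitor optional function `(ensemble, step)` called every 10 steps
#'   (e.g. to record a KL estimate).
#' @return Final [particle_ensemble()] with attributes `converged` (logical)
#'   and `steps`.
#' @export
svgd_sample <- function(V, init_ensemble, kernel = kernel_rbf(), dt = 0.1,
                        n_steps = 500, tol = 1e-6, monitor = NULL) {
  ens <- if (inherits(init_ensemble, "particle_ensemble")) {
    init_ensemble
  } else particle_ensemble(init_ensemble)
  converged <- FALSE
  k <- 0
  while (k < n_steps) {
    ens <- svgd_step(ens, V, kernel, dt)
    k <- k + 1
    if (!is.null(monitor) && k %% 10 == 0) monitor(ens, k)
    if (attr(ens, "max_displacement") < tol) {
      converged <- TRUE
      break
    }
  }
  attr(ens, "converged") <- converged
  attr(ens, "steps") <- k
  ens
}
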