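## Metropolis-family samplers targeting an arbitrary log-density
## (e.g. -V(theta) for a Gaussian posterior, or -f(theta)/2 for a CIL cost).

new_chain_ <- function(samples, log_target, accepted, proposal_cfg, seed) {
  colnames(samples) <- colnames(samples) %||%
    paste0("theta", seq_len(ncol(samples)))
  structure(list(samples = samples, log_target = log_target,
                 accepted = accepted, proposal_cfg = proposal_cfg,
                 seed = seed),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain> %d steps, d = %d, acceptance rate %.3f\n",
              nrow(x$samples), ncol(x$samples), mean(x$accepted)))
  invisible(x)
}

run_mh_ <- function(log_target, theta0, n_steps, seed, propose, log_q = NULL,
                    refresh = FALSE, proposal_cfg = list()) {
  d <- length(theta0)
  lt0 <- log_target(theta0)
  if (!is.finite(lt0)) {
    stop_cil("log_target is not finite at theta0", "cil_validation_error")
  }
  with_seed_(seed, {
    samples <- matrix(NA_real_, n_steps, d)
    ltv <- numeric(n_steps)
    acc <- logical(n_steps)
    cur <- theta0
    lcur <- lt0
    for (j in seq_len(n_steps)) {
      prop <- propose(cur, j)
      lprop <- log_target(prop)
      if (refresh) lcur <- log_target(cur)
      dl <- lprop - lcur
      if (!is.null(log_q)) dl <- dl + log_q(prop, cur) - log_q(cur, prop)
      if (is.finite(lprop) && log(runif(1)) < dl) {
        cur <- prop
        lcur <- lprop
        acc[j] <- TRUE
      }
      samples[j, ] <- cur
      ltv[j] <- lcur
    }
    if (!is.null(names(theta0))) colnames(samples) <- names(theta0)
    new_chain_(samples, ltv, acc, proposal_cfg, seed)
  })
}

#' Random-walk Metropolis sampler
#'
#' Gaussian random-walk proposal \eqn{\tilde\theta = \theta_j + Z},
#' \eqn{Z \sim N(0, s\,\mathrm{Id})}, accepted with probability
#' \eqn{\min(1, \exp(\log\pi(\tilde\theta) - \log\pi(\theta_j)))}. A rejected
#' step repeats the current state.
#'
#' @param log_target function returning the log target density (up to a
#'   constant); must be finite at `theta0`.
#' @param theta0 initial state (named vector names are kept).
#' @param step_s proposal variance `s` (scalar) of the isotropic Gaussian.
#' @param n_steps chain length.
#' @param seed integer seed; fixed seeds give bit-identical chains.
#' @param refresh if `TRUE`, the current state's (stochastic) log target is
#'   re-evaluated at every step instead of cached; relevant only for
#'   stochastic targets such as CIL costs.
#' @return An `mcmc_chain`: list with `samples`, `log_target`, `accepted`,
#'   `proposal_cfg`, `seed`.
#' @export
metropolis <- function(log_target, theta0, step_s, n_steps, seed,
                       refresh = FALSE) {
  stopifnot(step_s > 0)
  d <- length(theta0)
  s <- sqrt(step_s)
  run_mh_(log_target, theta0, n_steps, seed,
          propose = function(cur, j) cur + s * rnorm(d),
          refresh = refresh,
          proposal_cfg = list(algorithm = "metropolis", step_s = step_s))
}

#' Metropolis-Hastings sampler with a user-supplied proposal
#'
#' Uses the standard Hastings correction
#' \eqn{\min\{1, \exp(\Delta\log\pi + \log q(\theta_j \mid \tilde\theta)
#' - \log q(\tilde\theta \mid \theta_j))\}}, which reduces to the Metropolis
#' rule for symmetric proposals.
#'
#' @inheritParams metropolis
#' @param proposal list with `sample(theta)` drawing a candidate given the
#'   current state (using the ambient RNG) and `log_density(from, to)`
#'   evaluating \eqn{\log q(\mathrm{to} \mid \mathrm{from})}.
#' @return An `mcmc_chain`.
#' @export
metropolis_hastings <- function(log_target, proposal, theta0, n_steps, seed,
                                refresh = FALSE) {
  stopifnot(is.function(proposal$sample), is.function(proposal$log_density))
  run_mh_(log_target, theta0, n_steps, seed,
          propose = function(cur, j) proposal$sample(cur),
          log_q = proposal$log_density,
          refresh = refresh,
          proposal_cfg = list(algorithm = "metropolis-hastings"))
}

#' Adaptive Metropolis sampler
#'
#' Random-walk Metropolis whose proposal covariance tracks the chain history:
#' before step `t0` a fixed covariance `C0` is used; afterwards the proposal
#' is \eqn{N(0, s_d\,\mathrm{cov}(\theta_1,\dots,\theta_j) + s_d\,\epsilon\,I)}
#' with the scaling \eqn{s_d = 2.38^2/d}. The empirical covariance is updated
#' recursively in O(d^2) per step.
#'
#' @inheritParams metropolis
#' @param adapt_cfg list: `t0` (adaptation start, default 200), `sd` (scale,
#'   default `2.38^2/d`), `epsilon` (ridge, default 1e-8), `C0` (initial
#'   proposal covariance, default `0.1^2 I`).
#' @return An `mcmc_chain`; the final adapted covariance is stored in
#'   `proposal_cfg$C_final`.
#' @export
adaptive_metropolis <- function(log_target, theta0, n_steps,
                                adapt_cfg = list(), seed, refresh = FALSE) {
  d <- length(theta0)
  cfg <- modifyList(list(t0 = 200, sd = 2.38^2 / d, epsilon = 1e-8,
                         C0 = diag(0.1^2, d)), adapt_cfg)
  # t0 >= n_steps simply disables adaptation (pure random walk with C0)
  state <- new.env(parent = emptyenv())
  state$mean <- as.numeric(theta0)
  state$S <- matrix(0, d, d) # running sum of squared deviations (Welford)
  state$count <- 1
  state$R <- chol(cfg$C0)
  update_moments <- function(x) {
    state$count <- state$count + 1
    delta <- x - state$mean
    state$mean <- state$mean + delta / state$count
    state$S <- state$S + tcrossprod(delta, x - state$mean)
  }
  propose <- function(cur, j) {
    if (j > 1) update_moments(as.numeric(cur))
    if (j > cfg$t0 && state$count > d) {
      C <- cfg$sd * (state$S / (state$count - 1) + cfg$epsilon * diag(d))
      state$R <- chol(C)
    }
    cur + drop(rnorm(d) %*% state$R)
  }
  chain <- run_mh_(log_target, theta0, n_steps, seed, propose = propose,
                   refresh = refresh,
                   proposal_cfg = list(algorithm = "adaptive-metropolis",
                                       t0 = cfg$t0, sd = cfg$sd,
                                       epsilon = cfg$epsilon))
  # expose the recursive moments so the recursion can be checked against a
  # batch recomputation over the visited history (theta0, s_1, ..., s_{n-1})
  chain$proposal_cfg$cov_history <- state$S / max(state$count - 1, 1)
  chain$proposal_cfg$history_length <- state$count
  chain
}
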