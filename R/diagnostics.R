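## Chain diagnostics: acceptance rate, effective sample size, moments.

# ESS via the initial-positive-sequence estimator: sum autocorrelations of
# successive lag pairs until the first pair-sum goes negative.
ess_ <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(1)
  r <- acf(x, lag.max = min(n - 1, 10 * floor(sqrt(n))), plot = FALSE,
           demean = TRUE)$acf[, 1, 1]
  s <- 0
  k <- 1
  while (k + 1 < length(r)) {
    pair <- r[k + 1] + ifelse(k + 2 <= length(r), r[k + 2], 0)
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Summary diagnostics for an MCMC chain
#'
#' Discards the burn-in fraction, then reports the acceptance rate over the
#' full chain, per-dimension effective sample sizes (autocorrelation-sum
#' estimator truncated at the first negative lag pair), and posterior mean
#' and covariance of the retained samples. A constant (zero-variance)
#' dimension is flagged and assigned the minimal ESS of 1.
#'
#' @param chain an `mcmc_chain`.
#' @param burn_in_fraction fraction of initial samples discarded (default
#'   0.3); must leave at least two samples.
#' @return List with `acceptance_rate`, `ess`, `mean`, `cov`, `n_kept`,
#'   `degenerate` (logical per dimension).
#' @export
chain_diagnostics <- function(chain, burn_in_fraction = 0.3) {
  stopifnot(inherits(chain, "mcmc_chain"))
  n <- nrow(chain$samples)
  burn <- floor(burn_in_fraction * n)
  if (burn >= n - 1) {
    stop_cil("burn-in leaves fewer than two samples", "cil_validation_error")
  }
  kept <- chain$samples[(burn + 1):n, , drop = FALSE]
  ess <- apply(kept, 2L, ess_)
  degenerate <- apply(kept, 2L, function(x) var(x) == 0)
  list(acceptance_rate = mean(chain$accepted),
       ess = ess,
       mean = colMeans(kept),
       cov = cov(kept),
       n_kept = nrow(kept),
       degenerate = degenerate)
}

#' Central credible intervals from an MCMC chain
#'
#' Equal-tailed intervals of the marginal posteriors after burn-in removal.
#'
#' @inheritParams chain_diagnostics
#' @param level interval mass, default 0.95.
#' @return Matrix with columns `lower`, `upper`, one row per dimension.
#' @export
chain_credible_intervals <- function(chain, level = 0.95,
                                     burn_in_fraction = 0.3) {
  n <- nrow(chain$samples)
  burn <- floor(burn_in_fraction * n)
  kept <- chain$samples[(burn + 1):n, , drop = FALSE]
  a <- (1 - level) / 2
  t(apply(kept, 2L, quantile, probs = c(a, 1 - a), names = FALSE,
          type = 7)) -> ci
  colnames(ci) <- c("lower", "upper")
  ci
}
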