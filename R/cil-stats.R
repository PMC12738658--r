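## Gaussian statistics of correlation-integral vectors and the CIL / SCIL
## stochastic cost functions.

#' Forward-model wrapper for CIL evaluation
#'
#' Bundles a simulator with the information the cost functions need. For
#' `kind = "pattern"` the simulator must return a [pattern_ensemble()] of `n`
#' independent patterns; for `kind = "trajectory"` a [trajectory_set()] with
#' `n` sampled points.
#'
#' @param simulate function `(theta, n, seed)`.
#' @param kind `"pattern"` or `"trajectory"`.
#' @param metric pattern distance metric (pattern kind).
#' @param norm trajectory point norm (trajectory kind).
#' @param name descriptive label.
#' @return An object of class `cil_model`.
#' @export
cil_model <- function(simulate, kind = c("pattern", "trajectory"),
                      metric = "L2", norm = "L2", name = "model") {
  kind <- match.arg(kind)
  stopifnot(is.function(simulate))
  structure(list(simulate = simulate, kind = kind, metric = metric,
                 norm = norm, name = name), class = "cil_model")
}

partition_subsets_ <- function(training, n_ens, N = NULL, shuffle_seed = NULL) {
  if (inherits(training, "pattern_ensemble")) {
    items <- training$patterns
    navail <- length(items)
  } else if (inherits(training, "trajectory_set")) {
    navail <- nrow(training$states)
  } else {
    stop_cil("training must be a pattern_ensemble or trajectory_set",
             "cil_validation_error")
  }
  N <- N %||% (navail %/% n_ens)
  if (n_ens < 3) stop_cil("n_ens must be at least 3", "cil_validation_error")
  if (n_ens * N > navail || N < 1) {
    stop_cil(sprintf("need n_ens * N = %d items, have %d", n_ens * N, navail),
             "cil_validation_error")
  }
  idx <- seq_len(n_ens * N)
  if (!is.null(shuffle_seed)) {
    idx <- with_seed_(shuffle_seed, sample(navail))[seq_len(n_ens * N)]
  }
  blocks <- split(idx, rep(seq_len(n_ens), each = N))
  if (inherits(training, "pattern_ensemble")) {
    lapply(blocks, function(b) training$patterns[b])
  } else {
    lapply(blocks, function(b) {
      structure(list(times = training$times[b],
                     states = training$states[b, , drop = FALSE]),
                class = "trajectory_set")
    })
  }
}

subset_pair_ecdf_ <- function(s1, s2, bins, kind, metric = "L2", norm = "L2",
                              components = NULL) {
  if (kind == "pattern") {
    ecdf_patterns(pattern_cross_distances(s1, s2, metric), bins)
  } else {
    pairwise_ecdf_trajectories(s1, s2, bins, norm = norm,
                               components = components)
  }
}

regularise_covariance_ <- function(sigma, M, lambda = 1e-8) {
  repeat {
    reg <- sigma + lambda * (sum(diag(sigma)) / M + .Machine$double.eps) *
      diag(M)
    R <- tryCatch(chol(reg), error = function(e) NULL)
    if (!is.null(R)) return(list(sigma = reg, chol = R, lambda = lambda))
    lambda <- lambda * 10
    if (lambda > 1) {
      stop_cil("covariance regularisation failed", "cil_numerical_error")
    }
  }
}

#' Estimate the Gaussian statistics of the correlation-integral vector
#'
#' Partitions the training data into `n_ens` subsets of `N` items (contiguous
#' blocks in stored order, optionally after a seeded shuffle) and computes one
#' eCDF-vector realisation per unordered subset pair — `n_ens (n_ens - 1)/2`
#' realisations in total. Their sample mean and covariance define the limiting
#' Gaussian used by [cil_cost()]; the covariance is ridge-regularised by
#' `lambda * tr(Sigma)/M * I` (escalated tenfold until the Cholesky
#' factorisation succeeds).
#'
#' @param training a [pattern_ensemble()] or [trajectory_set()].
#' @param n_ens number of subsets (>= 3).
#' @param bins a [radius_bins()]; if `NULL`, bins are placed at quantiles of
#'   the pooled training distances via [select_radii()].
#' @param M number of bins when `bins` is `NULL`.
#' @param N subset size; defaults to `floor(available / n_ens)`.
#' @param metric,norm distances for pattern / trajectory mode.
#' @param components optional observed-component index (trajectory mode).
#' @param shuffle_seed optional seed for a pre-partition shuffle.
#' @param lambda initial regularisation weight.
#' @return An object of class `cil_statistics` with elements `mu`, `sigma`,
#'   `chol`, `bins`, `n_realisations`, `regularisation`, `kind`, `metric`,
#'   `norm`, `N` and the retained training `subsets`.
#' @export
estimate_statistics <- function(training, n_ens, bins = NULL, M = 10,
                                N = NULL, metric = "L2", norm = "L2",
                                components = NULL, shuffle_seed = NULL,
                                lambda = 1e-8) {
  kind <- if (inherits(training, "pattern_ensemble")) "pattern" else "trajectory"
  subsets <- partition_subsets_(training, n_ens, N, shuffle_seed)
  N <- if (kind == "pattern") length(subsets[[1]]) else nrow(subsets[[1]]$states)
  if (is.null(bins)) {
    pooled <- unlist(lapply(seq_len(n_ens - 1), function(k) {
      subset_pair_distances_(subsets[[k]], subsets[[k + 1]], kind, metric,
                             norm, components)
    }))
    bins <- select_radii(pooled, M = M)
  }
  pairs <- which(upper.tri(matrix(TRUE, n_ens, n_ens)), arr.ind = TRUE)
  Y <- t(vapply(seq_len(nrow(pairs)), function(r) {
    subset_pair_ecdf_(subsets[[pairs[r, 1]]], subsets[[pairs[r, 2]]], bins,
                      kind, metric, norm, components)$y
  }, numeric(bins$M)))
  n_real <- nrow(Y)
  if (n_real <= bins$M) {
    warning(sprintf(
      "only %d eCDF realisations for %d bins: covariance is rank-deficient and regularisation is load-bearing",
      n_real, bins$M))
  }
  mu <- colMeans(Y)
  sigma <- cov(Y)
  reg <- regularise_covariance_(sigma, bins$M, lambda)
  structure(list(mu = mu, sigma = reg$sigma, chol = reg$chol, bins = bins,
                 n_realisations = n_real, regularisation = reg$lambda,
                 kind = kind, metric = metric, norm = norm, N = N,
                 components = components, subsets = subsets,
                 realisations = Y),
            class = "cil_statistics")
}

#' Estimate correlation-integral statistics from independent simulations
#'
#' Monte-Carlo companion to [estimate_statistics()]: instead of partitioning
#' one observed dataset, it simulates `n_rep` fully independent pairs of
#' `N`-item subsets at `theta` and uses one eCDF realisation per pair. The
#' realisations are i.i.d., so the sample mean and covariance are unbiased
#' and the chi-squared calibration of the cost at the true parameter is clean
#' (the data-partition route reuses subsets across pairs, which correlates
#' the realisations and biases the covariance downward). All simulated
#' subsets are retained as training subsets for [cil_cost_at_parameter()].
#'
#' @param model a [cil_model()].
#' @param theta generating parameter.
#' @param n_rep number of independent pair realisations.
#' @param N subset size.
#' @param bins fixed [radius_bins()], or `NULL` to select them from the first
#'   few realisations' distances via [select_radii()].
#' @param M bin count when `bins` is `NULL`.
#' @param seed integer seed.
#' @param lambda initial covariance regularisation weight.
#' @return A `cil_statistics` object (see [estimate_statistics()]).
#' @export
estimate_statistics_sim <- function(model, theta, n_rep, N, bins = NULL,
                                    M = 10, seed = 1, lambda = 1e-8) {
  stopifnot(inherits(model, "cil_model"), n_rep >= 3)
  kind <- model$kind
  sets <- vector("list", 2L * n_rep)
  for (i in seq_along(sets)) {
    sim <- model$simulate(theta, N, derive_seed(seed, i))
    sets[[i]] <- if (kind == "pattern") sim$patterns else sim
  }
  dists <- function(i) {
    subset_pair_distances_(sets[[2 * i - 1]], sets[[2 * i]], kind,
                           model$metric, model$norm)
  }
  if (is.null(bins)) {
    bins <- select_radii(unlist(lapply(seq_len(min(10, n_rep)), dists)), M = M)
  }
  Y <- t(vapply(seq_len(n_rep), function(i) {
    ecdf_counts_(dists(i), bins$R)
  }, numeric(bins$M)))
  mu <- colMeans(Y)
  reg <- regularise_covariance_(cov(Y), bins$M, lambda)
  structure(list(mu = mu, sigma = reg$sigma, chol = reg$chol, bins = bins,
                 n_realisations = as.integer(n_rep), regularisation = reg$lambda,
                 kind = kind, metric = model$metric, norm = model$norm,
                 N = as.integer(N), components = NULL, subsets = sets,
                 realisations = Y),
            class = "cil_statistics")
}

subset_pair_distances_ <- function(s1, s2, kind, metric = "L2", norm = "L2",
                                   components = NULL) {
  if (kind == "pattern") {
    pattern_cross_distances(s1, s2, metric)
  } else {
    A <- s1$states; B <- s2$states
    if (!is.null(components)) {
      A <- A[, components, drop = FALSE]; B <- B[, components, drop = FALSE]
    }
    as.vector(cross_distances_(A, B, norm))
  }
}

#' @export
print.cil_statistics <- function(x, ...) {
  cat(sprintf(
    "<cil_statistics> %s mode, M = %d bins, %d realisations (N = %d), ridge %g\n",
    x$kind, x$bins$M, x$n_realisations, x$N, x$regularisation))
  invisible(x)
}

#' CIL cost: Mahalanobis distance of an eCDF vector
#'
#' The non-normalised negative log-likelihood
#' \eqn{f = (y - \mu)^\top \Sigma^{-1} (y - \mu)}, evaluated through the
#' cached Cholesky factor. At the true parameter, `f` is asymptotically
#' chi-squared with `M` degrees of freedom.
#'
#' @param y an [ecdf_vector()].
#' @param stats a `cil_statistics` object with matching bins.
#' @return Non-negative scalar cost.
#' @export
cil_cost <- function(y, stats) {
  stopifnot(inherits(y, "ecdf_vector"), inherits(stats, "cil_statistics"))
  if (!isTRUE(all.equal(y$bins$R, stats$bins$R))) {
    stop_cil("bins of y and stats differ", "cil_validation_error")
  }
  r <- y$y - stats$mu
  z <- forwardsolve(t(stats$chol), r)
  sum(z^2)
}

#' Evaluate the CIL cost at a candidate parameter
#'
#' Simulates fresh model output at `theta` (one trajectory of `N` points, or
#' `N` patterns), forms one eCDF-vector realisation against a seeded,
#' randomly chosen training subset retained inside `stats`, and returns the
#' Mahalanobis cost. The value is stochastic through the simulation seed;
#' fixed seeds make it reproducible.
#'
#' @param theta candidate parameter (named vector or [parameter_vector()]).
#' @param stats a `cil_statistics` object from [estimate_statistics()].
#' @param model a [cil_model()] whose `kind` matches `stats$kind`.
#' @param seed integer seed driving both the simulation and the subset draw.
#' @return Scalar cost.
#' @export
cil_cost_at_parameter <- function(theta, stats, model, seed) {
  stopifnot(inherits(stats, "cil_statistics"), inherits(model, "cil_model"))
  if (model$kind != stats$kind) {
    stop_cil("model kind does not match statistics kind",
             "cil_validation_error")
  }
  k <- with_seed_(derive_seed(seed, 1), sample.int(length(stats$subsets), 1))
  sim <- model$simulate(theta, stats$N, derive_seed(seed, 2))
  y <- subset_pair_ecdf_(sim, stats$subsets[[k]], stats$bins, stats$kind,
                         stats$metric, stats$norm, stats$components)
  cil_cost(y, stats)
}

#' SCIL cost: synthetic correlation-integral likelihood
#'
#' Limited-data variant: the Gaussian statistics are estimated from repeated
#' simulations at the candidate parameter, and the data contribute a single
#' eCDF realisation. One simulated reference subset of `N` items is drawn at
#' `theta` and held fixed; each of the `n_rep` synthetic realisations pairs
#' `n_data` fresh, fully independent simulations against this reference, and
#' the data vector pairs the `n_data` observed items against the same
#' reference. Conditional on the reference subset the synthetic realisations
#' are therefore i.i.d. copies of the data vector's distribution at the true
#' parameter, which keeps the cost approximately chi-squared with `M` degrees
#' of freedom even for a single data snapshot.
#'
#' @param theta candidate parameter.
#' @param data observed data: a [pattern_ensemble()] (any size, down to one
#'   pattern) or a [trajectory_set()] (one observed trajectory).
#' @param model a [cil_model()].
#' @param N reference-subset size paired against the data.
#' @param n_rep number of synthetic eCDF realisations for the mean and
#'   covariance estimate.
#' @param bins fixed [radius_bins()]; if `NULL`, selected per evaluation from
#'   the first synthetic realisations' distances via [select_radii()].
#' @param M bin count when `bins` is `NULL`.
#' @param seed integer seed.
#' @param lambda initial covariance regularisation weight.
#' @return Scalar cost with attribute `"M"` (the bin count used).
#' @export
scil_cost <- function(theta, data, model, N = 20, n_rep = 150,
                      bins = NULL, M = 5, seed = 1, lambda = 1e-6) {
  stopifnot(inherits(model, "cil_model"))
  kind <- model$kind
  if (kind == "pattern") {
    if (!inherits(data, "pattern_ensemble")) {
      stop_cil("pattern model requires pattern_ensemble data",
               "cil_validation_error")
    }
    n_data <- length(data$patterns)
    data_items <- data$patterns
  } else {
    if (!inherits(data, "trajectory_set")) {
      stop_cil("trajectory model requires trajectory_set data",
               "cil_validation_error")
    }
    n_data <- nrow(data$states)
    data_items <- data
  }
  # fixed simulated reference subset
  ref <- if (kind == "pattern") {
    model$simulate(theta, N, derive_seed(seed, 1))$patterns
  } else {
    model$simulate(theta, N, derive_seed(seed, 1))
  }
  dist_to_ref <- function(items) {
    if (kind == "pattern") {
      pattern_cross_distances(items, ref, model$metric)
    } else {
      as.vector(cross_distances_(items$states, ref$states, model$norm))
    }
  }
  draw_items <- function(i) {
    if (kind == "pattern") {
      model$simulate(theta, n_data, derive_seed(seed, 1 + i))$patterns
    } else {
      model$simulate(theta, n_data, derive_seed(seed, 1 + i))
    }
  }
  D <- lapply(seq_len(n_rep), function(i) dist_to_ref(draw_items(i)))
  if (is.null(bins)) {
    bins <- select_radii(unlist(D[seq_len(min(10, n_rep))]), M = M)
  }
  Y <- t(vapply(D, function(d) ecdf_counts_(d, bins$R), numeric(bins$M)))
  mu <- colMeans(Y)
  reg <- regularise_covariance_(cov(Y), bins$M, lambda)
  r <- ecdf_counts_(dist_to_ref(data_items), bins$R) - mu
  z <- forwardsolve(t(reg$chol), r)
  structure(sum(z^2), M = bins$M)
}

#' Chi-squared calibration report for replicate CIL costs
#'
#' At the true parameter the CIL cost is asymptotically \eqn{\chi^2(M)}; this
#' reports the mean cost relative to its expectation `M` and a
#' Kolmogorov-Smirnov comparison against the reference distribution.
#'
#' @param costs non-negative replicate costs (>= 50 recommended).
#' @param M degrees of freedom (number of bins).
#' @return List with `mean_ratio`, `ks_statistic`, `ks_pvalue`, `n`.
#' @export
chi2_calibration <- function(costs, M) {
  stopifnot(all(costs >= 0))
  ks <- suppressWarnings(ks.test(costs, pchisq, df = M))
  list(mean_ratio = mean(costs) / M,
       ks_statistic = unname(ks$statistic),
       ks_pvalue = ks$p.value,
       n = length(costs))
}
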