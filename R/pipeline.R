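## Run configuration validation and the end-to-end pipeline
## (simulate -> build likelihood -> sample -> diagnose).

config_defaults_ <- function() {
  list(
    model = list(name = "turing",
                 theta = NULL,
                 grid = list(nx = 64, length = 40),
                 ic_amplitude = 0.01,
                 r_max = 3, n_r = 120,
                 times = seq(0, 20, by = 2),
                 n_points = 100, dt_sample = 0.25, epsilon = 1e-2,
                 solver = list()),
    likelihood = list(mode = "cil", M = 10, n_ens = 16, N = 10,
                      metric = "L2",
                      scil = list(N = 20, n_rep = 120, M = 5),
                      prior_mean = NULL, prior_sd = 2),
    sampler = list(algorithm = "adaptive_metropolis", steps = 1000,
                   seed = 1L, step_s = 0.01, t0 = 200,
                   sample_params = NULL, init = NULL,
                   burn_in_fraction = 0.3, refresh = FALSE),
    output = list(dir = NULL, overwrite = FALSE))
}

# simple FNV-1a hash of a string, for provenance stamps (no external deps)
fnv1a_ <- function(s) {
  h <- 84696351
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2147483648 # stay inside the 32-bit signed range
  }
  sprintf("%08x", as.integer(h))
}

#' Validate and normalise a run configuration
#'
#' Accepts a YAML file path or a nested list, fills documented defaults,
#' rejects unknown sections and keys, and enforces cross-field constraints
#' (e.g. `n_ens >= 3` for the subset-pair construction of the CIL
#' statistics). All errors are collected before failing. Normalisation is
#' idempotent.
#'
#' @param x path to a YAML config file, or a nested list.
#' @return A normalised config (class `run_config`), or an error of class
#'   `cil_config_error` whose `errors` field lists every problem found.
#' @export
validate_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  x <- unclass(x)
  defaults <- config_defaults_()
  errs <- character(0)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    errs <- c(errs, sprintf("unknown section(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (sec in intersect(names(x), names(defaults))) {
    bad <- setdiff(names(x[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      errs <- c(errs, sprintf("unknown key(s) in [%s]: %s", sec,
                              paste(bad, collapse = ", ")))
    }
    cfg[[sec]] <- modifyList(defaults[[sec]],
                             x[[sec]][intersect(names(x[[sec]]),
                                                names(defaults[[sec]]))],
                             keep.null = TRUE)
  }
  if (!cfg$model$name %in% c("turing", "lorenz63", "colony")) {
    errs <- c(errs, sprintf("unknown model '%s'", cfg$model$name))
  }
  if (!cfg$likelihood$mode %in% c("bayes", "cil", "scil")) {
    errs <- c(errs, sprintf("unknown likelihood mode '%s'",
                            cfg$likelihood$mode))
  }
  if (cfg$likelihood$mode == "bayes" && cfg$model$name != "colony") {
    errs <- c(errs, "bayes mode requires the colony model")
  }
  if (cfg$likelihood$mode == "cil" && cfg$likelihood$n_ens < 3) {
    errs <- c(errs, sprintf(
      "n_ens = %d: the subset-pair covariance estimate requires n_ens >= 3",
      cfg$likelihood$n_ens))
  }
  if (cfg$likelihood$M < 2) errs <- c(errs, "M must be >= 2")
  if (cfg$likelihood$N < 1) errs <- c(errs, "N must be >= 1")
  if (cfg$sampler$steps < 10) errs <- c(errs, "sampler steps must be >= 10")
  if (!cfg$sampler$algorithm %in% c("metropolis", "adaptive_metropolis")) {
    errs <- c(errs, sprintf("unknown sampler algorithm '%s'",
                            cfg$sampler$algorithm))
  }
  seed <- cfg$sampler$seed
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    errs <- c(errs, "sampler seed must be a single integer")
  }
  cfg$sampler$seed <- as.integer(seed)
  if (is.null(cfg$model$theta)) {
    cfg$model$theta <- switch(cfg$model$name,
      turing = as.list(schnakenberg_params()),
      lorenz63 = as.list(chaotic_system("lorenz63")$default_theta),
      colony = list(alpha = 0.3, sigma_k = 0.15, sigma_s = 0.25,
                    sigma_o = 0.05))
  }
  if (is.null(cfg$sampler$sample_params)) {
    cfg$sampler$sample_params <- switch(cfg$model$name,
      turing = "Dv", lorenz63 = "rho",
      colony = c("alpha", "sigma_k", "sigma_s", "sigma_o"))
  }
  if (length(errs) > 0) {
    stop(structure(class = c("cil_config_error", "cilinfer_error", "error",
                             "condition"),
                   list(message = paste(errs, collapse = "; "),
                        call = sys.call(-1), errors = errs)))
  }
  structure(cfg, class = "run_config")
}

log10_prior_defaults_ <- function() {
  # wide Gaussian priors on the log scale for the colony parameters
  list(mean = c(log_alpha = -1.5, log_sigma_k2 = -3.5, log_sigma_s2 = -2.5,
                log_sigma_o2 = -5.5),
       sd = 2)
}

#' Log-posterior for the colony model on the log-parameter scale
#'
#' Builds the function \eqn{\phi \mapsto \log \ell(D \mid \theta(\phi)) +
#' \log \pi(\phi)} sampled by the Metropolis family, where
#' \eqn{\phi = (\log\alpha, \log\sigma_k^2, \log\sigma_s^2, \log\sigma_o^2)}
#' and the prior is Gaussian in \eqn{\phi}.
#'
#' @param meas a `radius_measurements` data frame.
#' @param prior_mean,prior_sd Gaussian prior on \eqn{\phi}; defaults are wide
#'   (sd 2) around biologically plausible magnitudes.
#' @param r_max,n_r,solver_cfg forwarded to the colony solver.
#' @return Function `phi -> log posterior` (unnormalised).
#' @export
colony_log_posterior <- function(meas, prior_mean = NULL, prior_sd = 2,
                                 r_max = 3, n_r = 120, solver_cfg = list()) {
  pd <- log10_prior_defaults_()
  prior_mean <- prior_mean %||% pd$mean
  prior <- gaussian_prior(prior_mean, diag(prior_sd^2, 4))
  function(phi) {
    theta <- c(alpha = exp(phi[1]), sigma_k = exp(phi[2] / 2),
               sigma_s = exp(phi[3] / 2), sigma_o = exp(phi[4] / 2))
    ll <- suppressWarnings(
      colony_loglik(meas, theta, r_max = r_max, n_r = n_r,
                    solver_cfg = solver_cfg))
    if (!is.finite(ll)) return(-Inf)
    ll + log_prior(phi, prior)
  }
}

pipeline_model_ <- function(cfg) {
  theta0 <- unlist(cfg$model$theta)
  if (cfg$model$name == "turing") {
    cil_model(function(theta, n, seed) {
      simulate_turing_ensemble(n, theta = theta, grid = cfg$model$grid,
                               ic_amplitude = cfg$model$ic_amplitude,
                               seed = seed, solver_cfg = cfg$model$solver)
    }, kind = "pattern", metric = cfg$likelihood$metric, name = "turing")
  } else {
    dt_s <- cfg$model$dt_sample
    cil_model(function(theta, n, seed) {
      x0 <- perturb_initial_state(chaotic_system("lorenz63")$default_x0,
                                  cfg$model$epsilon, seed)
      times <- c(0, 5 + dt_s * (0:(n - 1)))
      ts <- simulate_chaotic(theta, x0, times)
      trajectory_set(ts$times[-1], ts$states[-1, , drop = FALSE])
    }, kind = "trajectory", norm = cfg$likelihood$metric, name = "lorenz63")
  }
}

# log-target wrapping a stochastic CIL cost; each evaluation draws a fresh
# derived seed so the cost noise is independent across proposals
stochastic_cil_target_ <- function(stats, model, theta0, sample_params,
                                   base_seed) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0
  function(phi) {
    counter$i <- counter$i + 1
    theta <- theta0
    theta[sample_params] <- exp(phi)
    -0.5 * cil_cost_at_parameter(theta, stats, model,
                                 seed = derive_seed(base_seed, counter$i))
  }
}

#' Run the configured inference pipeline
#'
#' Executes simulate, build-likelihood, sample and diagnose stages as
#' configured, writing the chain (delimited text plus JSON sidecar), a
#' diagnostics report and a provenance log into the output directory. Any
#' stage failure aborts with an error naming the stage; files already
#' written are kept alongside a `.partial` marker.
#'
#' @param config a `run_config` from [validate_config()], a list, or a YAML
#'   path.
#' @return Invisible list with the chain, diagnostics and file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- cfg$output$dir %||% tempfile("cil_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  seed <- cfg$sampler$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_cil(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "cil_pipeline_error")
    })
  }
  theta0 <- unlist(cfg$model$theta)
  sp <- cfg$sampler$sample_params

  if (cfg$likelihood$mode == "bayes") {
    meas <- stage("simulate", {
      r_true <- colony_forward_radii(theta0[c("alpha", "sigma_k", "sigma_s")],
                                     cfg$model$times, r_max = cfg$model$r_max,
                                     n_r = cfg$model$n_r)
      observe_radius(r_true, theta0[["sigma_o"]], derive_seed(seed, 11),
                     times = cfg$model$times)
    })
    write_delim_artifact(meas, file.path(out_dir, "radius_measurements.csv"))
    log_target <- stage("build-likelihood",
                        colony_log_posterior(meas,
                                             prior_mean = cfg$likelihood$prior_mean,
                                             prior_sd = cfg$likelihood$prior_sd,
                                             r_max = cfg$model$r_max,
                                             n_r = cfg$model$n_r))
    phi0 <- cfg$sampler$init %||%
      log(c(theta0[["alpha"]], theta0[["sigma_k"]]^2, theta0[["sigma_s"]]^2,
            theta0[["sigma_o"]]^2))
  } else if (cfg$likelihood$mode == "cil") {
    model <- pipeline_model_(cfg)
    stats <- stage("build-likelihood", {
      if (model$kind == "pattern") {
        training <- model$simulate(theta0, cfg$likelihood$n_ens * cfg$likelihood$N,
                                   derive_seed(seed, 21))
        estimate_statistics(training, n_ens = cfg$likelihood$n_ens,
                            M = cfg$likelihood$M, metric = cfg$likelihood$metric)
      } else {
        training <- model$simulate(theta0,
                                   cfg$likelihood$n_ens * cfg$likelihood$N,
                                   derive_seed(seed, 21))
        estimate_statistics(training, n_ens = cfg$likelihood$n_ens,
                            M = cfg$likelihood$M, norm = cfg$likelihood$metric)
      }
    })
    write_cil_statistics(stats, file.path(out_dir, "cil_statistics.json"))
    log_target <- stochastic_cil_target_(stats, model, theta0, sp,
                                         derive_seed(seed, 31))
    phi0 <- cfg$sampler$init %||% log(unname(theta0[sp]))
  } else { # scil
    model <- pipeline_model_(cfg)
    sc <- cfg$likelihood$scil
    data <- stage("simulate",
                  model$simulate(theta0, 1, derive_seed(seed, 41)))
    counter <- new.env(parent = emptyenv()); counter$i <- 0
    log_target <- function(phi) {
      counter$i <- counter$i + 1
      theta <- theta0
      theta[sp] <- exp(phi)
      -0.5 * scil_cost(theta, data, model, N = sc$N, n_rep = sc$n_rep,
                       M = sc$M,
                       seed = derive_seed(derive_seed(seed, 51), counter$i))
    }
    phi0 <- cfg$sampler$init %||% log(unname(theta0[sp]))
  }

  chain <- stage("sample", {
    if (cfg$sampler$algorithm == "metropolis") {
      metropolis(log_target, phi0, cfg$sampler$step_s, cfg$sampler$steps,
                 seed = seed, refresh = cfg$sampler$refresh)
    } else {
      adaptive_metropolis(log_target, phi0, cfg$sampler$steps,
                          adapt_cfg = list(t0 = cfg$sampler$t0,
                                           C0 = diag(cfg$sampler$step_s,
                                                     length(phi0))),
                          seed = seed, refresh = cfg$sampler$refresh)
    }
  })
  diag <- stage("diagnose",
                chain_diagnostics(chain, cfg$sampler$burn_in_fraction))

  chain_path <- file.path(out_dir, "chain.csv")
  write_delim_artifact(chain, chain_path)
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  jsonlite::write_json(
    list(seed = seed, acceptance_rate = diag$acceptance_rate,
         algorithm = cfg$sampler$algorithm, steps = cfg$sampler$steps,
         config_hash = fnv1a_(cfg_yaml)),
    file.path(out_dir, "chain.json"), auto_unbox = TRUE, digits = I(17))
  jsonlite::write_json(
    list(acceptance_rate = diag$acceptance_rate, ess = diag$ess,
         mean = diag$mean, cov = as.vector(diag$cov), n_kept = diag$n_kept),
    file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = I(17))
  writeLines(c(sprintf("config_hash: %s", fnv1a_(cfg_yaml)),
               sprintf("seed: %d", seed),
               sprintf("package: cilinfer %s",
                       as.character(packageVersion("cilinfer"))),
               cfg_yaml),
             file.path(out_dir, "provenance.log"))
  unlink(marker)
  invisible(list(chain = chain, diagnostics = diag, dir = out_dir,
                 config = cfg))
}
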