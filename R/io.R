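## Serialisation: CIL statistics containers, tabular artifacts, fixtures.

#' Write / read CIL statistics
#'
#' Round-trips a `cil_statistics` object through a JSON container holding the
#' bins, mean, covariance, eCDF realisations and (optionally) the retained
#' training subsets, at full double precision.
#'
#' @param stats a `cil_statistics` object.
#' @param path file path.
#' @param include_training if `TRUE` (default) the training subsets are
#'   stored too, so reloaded statistics remain usable by
#'   [cil_cost_at_parameter()].
#' @return `write_cil_statistics()`: the path, invisibly;
#'   `read_cil_statistics()`: the reconstructed `cil_statistics`.
#' @export
write_cil_statistics <- function(stats, path, include_training = TRUE) {
  stopifnot(inherits(stats, "cil_statistics"))
  ser_subset <- function(s) {
    if (stats$kind == "pattern") {
      lapply(s, function(p) list(dim = if (is.null(dim(p))) length(p) else dim(p),
                                 data = as.vector(p)))
    } else {
      list(times = s$times, states = as.vector(s$states),
           dim = dim(s$states))
    }
  }
  obj <- list(
    container = "cil_statistics",
    kind = stats$kind, metric = stats$metric, norm = stats$norm,
    M = stats$bins$M, bins = stats$bins$R,
    n_realisations = stats$n_realisations, N = stats$N,
    regularisation = stats$regularisation,
    components = stats$components,
    mu = stats$mu, sigma = as.vector(stats$sigma),
    realisations = as.vector(stats$realisations),
    subsets = if (include_training) lapply(stats$subsets, ser_subset))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_cil_statistics
#' @export
read_cil_statistics <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$container, "cil_statistics")) {
    stop_cil("not a cil_statistics container", "cil_validation_error")
  }
  num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  M <- as.integer(obj$M)
  bins <- radius_bins(num(obj$bins))
  sigma <- matrix(num(obj$sigma), M, M)
  subsets <- NULL
  if (!is.null(obj$subsets)) {
    subsets <- lapply(obj$subsets, function(s) {
      if (obj$kind == "pattern") {
        lapply(s, function(p) {
          d <- as.integer(unlist(p$dim))
          if (length(d) > 1) array(num(p$data), dim = d) else num(p$data)
        })
      } else {
        structure(list(times = num(s$times),
                       states = matrix(num(s$states),
                                       nrow = as.integer(unlist(s$dim))[1])),
                  class = "trajectory_set")
      }
    })
  }
  structure(list(mu = num(obj$mu), sigma = sigma, chol = chol(sigma),
                 bins = bins,
                 n_realisations = as.integer(obj$n_realisations),
                 regularisation = as.numeric(obj$regularisation),
                 kind = obj$kind, metric = obj$metric, norm = obj$norm,
                 N = as.integer(obj$N),
                 components = if (!is.null(obj$components)) {
                   unlist(obj$components)
                 },
                 subsets = subsets,
                 realisations = if (!is.null(obj$realisations)) {
                   matrix(num(obj$realisations), ncol = M)
                 }),
            class = "cil_statistics")
}

#' Write tabular artifacts as delimited text
#'
#' Trajectory sets and radius measurements are written as comma-separated
#' text with a header row and `time` as the first column; chains carry the
#' parameter columns plus `log_target` and `accepted`.
#'
#' @param x object to write.
#' @param path file path.
#' @param ... unused.
#' @return The path, invisibly.
#' @export
write_delim_artifact <- function(x, path, ...) UseMethod("write_delim_artifact")

#' @export
write_delim_artifact.trajectory_set <- function(x, path, ...) {
  df <- data.frame(time = x$times, x$states)
  names(df) <- c("time", paste0("x", seq_len(ncol(x$states))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_delim_artifact.radius_measurements <- function(x, path, ...) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_delim_artifact.mcmc_chain <- function(x, path, ...) {
  df <- data.frame(x$samples, log_target = x$log_target,
                   accepted = as.integer(x$accepted))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_delim_artifact.particle_ensemble <- function(x, path, ...) {
  df <- data.frame(x$positions)
  names(df) <- paste0("theta", seq_len(ncol(x$positions)))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(time = x$time, n_particles = nrow(x$positions),
                            weights = "uniform"),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @export
write_delim_artifact.cil_statistics <- function(x, path, ...) {
  # eCDF realisations with their bin radii, for external plotting
  df <- as.data.frame(x$realisations)
  names(df) <- sprintf("R_%g", x$bins$R)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a distance sample as delimited text
#'
#' @param d numeric vector of distances.
#' @param path file path.
#' @param metric metric identifier recorded in the header column name.
#' @return The path, invisibly.
#' @export
write_distance_sample <- function(d, path, metric = "L2") {
  df <- data.frame(distance = as.numeric(d))
  attr(df, "metric") <- metric
  names(df) <- paste0("distance_", metric)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory set from delimited text
#'
#' @param path CSV with `time` first column and state columns.
#' @return A [trajectory_set()].
#' @export
read_trajectory_set <- function(path) {
  df <- read.csv(path)
  trajectory_set(df$time, as.matrix(df[, -1, drop = FALSE]))
}

#' Read radius measurements from delimited text
#'
#' @param path CSV with columns `time`, `r_obs` and optionally `r_true`.
#' @return A `radius_measurements` data frame.
#' @export
read_radius_measurements <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time", "r_obs") %in% names(df)))
  class(df) <- c("radius_measurements", "data.frame")
  df
}

#' Generate a synthetic data fixture on disk
#'
#' Emits one of the synthetic datasets the package's inference is exercised
#' on (a radius-measurement table, a chaotic trajectory set, or a Turing
#' pattern ensemble) together with a JSON manifest recording the generating
#' parameters, sizes and seeds. Regenerating from the same spec is
#' byte-identical.
#'
#' @param spec list with `type` (`"radius"`, `"trajectory"` or
#'   `"patterns"`), `theta` (named generating parameters), `seed`, plus
#'   type-specific sizes: `times` (radius), `n_points`/`dt_sample`
#'   (trajectory), `n`/`grid` (patterns).
#' @param dir output directory (created if needed).
#' @param overwrite refuse to overwrite existing files unless `TRUE`.
#' @return Invisible list of the files written (manifest last).
#' @export
generate_fixture <- function(spec, dir, overwrite = FALSE) {
  stopifnot(is.list(spec), !is.null(spec$type))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    path <- file.path(dir, name)
    if (file.exists(path) && !overwrite) {
      stop_cil(sprintf("refusing to overwrite '%s' (use overwrite = TRUE)",
                       path), "cil_validation_error")
    }
    files <<- c(files, path)
    path
  }
  seed <- spec$seed %||% 1L
  if (spec$type == "radius") {
    theta <- spec$theta
    times <- spec$times %||% seq(0, 20, by = 2)
    r_true <- colony_forward_radii(theta[c("alpha", "sigma_k", "sigma_s")],
                                   times,
                                   r_max = spec$r_max %||% 3,
                                   n_r = spec$n_r %||% 120)
    meas <- observe_radius(r_true, theta[["sigma_o"]], seed, times = times)
    write_delim_artifact(meas, emit("radius_measurements.csv"))
  } else if (spec$type == "trajectory") {
    n_points <- spec$n_points %||% 200
    dt_sample <- spec$dt_sample %||% 0.25
    t_transient <- spec$t_transient %||% 5
    times <- t_transient + dt_sample * (0:(n_points - 1))
    x0 <- perturb_initial_state(chaotic_system(spec$system %||% "lorenz63")$default_x0,
                                spec$epsilon %||% 1e-2, seed)
    ts <- simulate_chaotic(spec$theta, x0, c(0, times),
                           system = spec$system %||% "lorenz63")
    ts <- trajectory_set(ts$times[-1], ts$states[-1, , drop = FALSE])
    write_delim_artifact(ts, emit("trajectory.csv"))
  } else if (spec$type == "patterns") {
    n <- spec$n %||% 10
    ens <- simulate_turing_ensemble(n, theta = spec$theta %||% schnakenberg_params(),
                                    grid = spec$grid %||% list(nx = 64, length = 40),
                                    ic_amplitude = spec$ic_amplitude %||% 0.01,
                                    seed = seed)
    for (i in seq_len(n)) {
      p <- ens$patterns[[i]]
      write.csv(data.frame(value = as.vector(p)),
                emit(sprintf("pattern_%03d.csv", i)), row.names = FALSE)
    }
  } else {
    stop_cil(sprintf("unknown fixture type '%s'", spec$type),
             "cil_validation_error")
  }
  manifest <- list(generator = "cilinfer::generate_fixture",
                   version = as.character(packageVersion("cilinfer")),
                   spec = spec, files = basename(files))
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
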