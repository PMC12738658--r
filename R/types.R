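#' Named parameter vector
#'
#' Light-weight container for the parameters \eqn{\theta} of a forward model.
#' Components flagged `log_scale` store the natural logarithm of a positive
#' physical parameter; [param_values()] undoes the transform.
#'
#' @param values named numeric vector (finite).
#' @param log_scale logical vector (recycled) flagging which components are
#'   stored on the log scale.
#' @return An object of class `parameter_vector`.
#' @export
#' @examples
#' th <- parameter_vector(c(alpha = log(0.3), sigma_k = log(0.15)),
#'                        log_scale = TRUE)
#' param_values(th)
parameter_vector <- function(values, log_scale = FALSE) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop_cil("parameter_vector requires named values", "cil_validation_error")
  }
  check_finite(values, "parameter values")
  log_scale <- rep_len(as.logical(log_scale), length(values))
  structure(list(names = names(values), values = unname(as.numeric(values)),
                 log_scale = log_scale),
            class = "parameter_vector")
}

#' @rdname parameter_vector
#' @param theta a `parameter_vector` or a named numeric vector (taken to be on
#'   the natural scale).
#' @return `param_values()`: named numeric vector on the natural (physical)
#'   scale.
#' @export
param_values <- function(theta) {
  if (inherits(theta, "parameter_vector")) {
    v <- theta$values
    v[theta$log_scale] <- exp(v[theta$log_scale])
    names(v) <- theta$names
    return(v)
  }
  if (is.numeric(theta) && !is.null(names(theta))) return(theta)
  stop_cil("theta must be a parameter_vector or named numeric vector",
           "cil_validation_error")
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat("<parameter_vector>\n")
  print(param_values(x))
  invisible(x)
}

#' Trajectory set
#'
#' A set of state vectors sampled at strictly increasing times from one run of
#' a dynamical system.
#'
#' @param times strictly increasing numeric vector of length N >= 2.
#' @param states N x n numeric matrix; row i is the state at `times[i]`.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(times, states) {
  states <- as.matrix(states)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop_cil("times must be strictly increasing with length >= 2",
             "cil_validation_error")
  }
  if (nrow(states) != length(times)) {
    stop_cil("states must have one row per time point", "cil_validation_error")
  }
  check_finite(states, "trajectory states")
  structure(list(times = as.numeric(times), states = states),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> N = %d points, state dimension %d, t in [%g, %g]\n",
              nrow(x$states), ncol(x$states), min(x$times), max(x$times)))
  invisible(x)
}

#' Pattern ensemble
#'
#' A collection of spatial patterns on one fixed grid, all generated at a
#' single parameter value. Patterns are stored as numeric arrays (vectors for
#' 1-D grids, matrices for 2-D grids).
#'
#' @param patterns list of numeric arrays of identical dimensions.
#' @param grid_shape integer vector of spatial dimensions; defaults to the
#'   shape of the first pattern.
#' @param component_mask character vector naming the observed model
#'   components (metadata).
#' @param normalised logical; `TRUE` if patterns were rescaled to zero mean /
#'   unit range before storage.
#' @return An object of class `pattern_ensemble`.
#' @export
pattern_ensemble <- function(patterns, grid_shape = NULL,
                             component_mask = "u", normalised = FALSE) {
  if (!is.list(patterns) || length(patterns) < 1L) {
    stop_cil("patterns must be a non-empty list", "cil_validation_error")
  }
  shp <- function(p) if (is.null(dim(p))) length(p) else dim(p)
  grid_shape <- grid_shape %||% shp(patterns[[1]])
  for (p in patterns) {
    if (!identical(as.integer(shp(p)), as.integer(grid_shape))) {
      stop_cil("all patterns must share grid_shape", "cil_validation_error")
    }
    check_finite(p, "pattern values")
  }
  structure(list(patterns = patterns, grid_shape = as.integer(grid_shape),
                 component_mask = component_mask, normalised = normalised),
            class = "pattern_ensemble")
}

#' @export
print.pattern_ensemble <- function(x, ...) {
  cat(sprintf("<pattern_ensemble> n = %d patterns on grid [%s], components: %s\n",
              length(x$patterns), paste(x$grid_shape, collapse = " x "),
              paste(x$component_mask, collapse = ", ")))
  invisible(x)
}

#' @export
length.pattern_ensemble <- function(x) length(x$patterns)
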