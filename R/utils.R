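## Internal helpers shared across modules.

# Evaluate `expr` under a local, fully specified RNG state. All stochastic
# operations in the package funnel through this, so nothing depends on (or
# disturbs) the caller's global RNG.
with_seed_ <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range. Used when one user-facing seed must drive several
# independent stochastic sub-steps.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629)
}

stop_cil <- function(msg, class, ...) {
  stop(structure(class = c(class, "cilinfer_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_cil(sprintf("non-finite values in %s", what), "cil_validation_error")
  }
  invisible(x)
}

# Trapezoidal quadrature on an arbitrary (typically uniform) grid.
trapz_ <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

cumtrapz_ <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Symmetric positive-definite solve via a cached Cholesky factor.
chol_solve_ <- function(R, b) {
  backsolve(R, forwardsolve(t(R), b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
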