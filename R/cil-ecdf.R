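## Generalised correlation-integral (eCDF) vectors and their ingredients.

#' Radius bins for correlation-integral vectors
#'
#' @param R strictly increasing vector of positive bin radii, length >= 2.
#' @return An object of class `radius_bins`.
#' @export
radius_bins <- function(R) {
  R <- as.numeric(R)
  if (length(R) < 2L || any(R <= 0) || any(diff(R) <= 0)) {
    stop_cil("bins must be positive, strictly increasing, length >= 2",
             "cil_validation_error")
  }
  structure(list(R = R, M = length(R)), class = "radius_bins")
}

#' @export
print.radius_bins <- function(x, ...) {
  cat(sprintf("<radius_bins> M = %d radii in [%g, %g]\n", x$M, x$R[1],
              x$R[x$M]))
  invisible(x)
}

#' eCDF vector at fixed radii
#'
#' Internal constructor shared by the trajectory and pattern routes; enforces
#' the defining invariants (components in \[0, 1\], non-decreasing).
#'
#' @param y numeric vector of eCDF values, one per bin.
#' @param bins a [radius_bins()].
#' @param source descriptor of how the vector was formed.
#' @return An object of class `ecdf_vector`.
#' @export
ecdf_vector <- function(y, bins, source = "unknown") {
  stopifnot(inherits(bins, "radius_bins"), length(y) == bins$M)
  if (any(y < 0 | y > 1) || any(diff(y) < 0)) {
    stop_cil("eCDF vector must be in [0,1] and non-decreasing",
             "cil_validation_error")
  }
  structure(list(y = as.numeric(y), bins = bins, source = source),
            class = "ecdf_vector")
}

#' @export
print.ecdf_vector <- function(x, ...) {
  cat(sprintf("<ecdf_vector> M = %d (%s)\n", x$bins$M, x$source))
  print(signif(x$y, 4))
  invisible(x)
}

# counts of values strictly below each bin radius, divided by n
ecdf_counts_ <- function(d, R) {
  # findInterval on -d against -rev(R) would also work; keep it transparent
  vapply(R, function(r) sum(d < r), numeric(1)) / length(d)
}

#' Correlation-integral vector of two trajectories
#'
#' Component k is the fraction of ordered point pairs (one point from each
#' trajectory) at distance strictly below the k-th bin radius:
#' \deqn{y_k = N^{-2} \#\{(i,j) : \|s_i - \tilde s_j\| < R_k\}.}
#' With `S == S_tilde` the components are the classical correlation sums of
#' the attractor.
#'
#' @param S,S_tilde [trajectory_set()] objects with equal state dimension.
#' @param bins a [radius_bins()].
#' @param norm distance norm: `"L2"` (default), `"L1"` or `"Linf"`.
#' @param components optional integer/logical index of observed state
#'   components (partial observation); default uses all.
#' @return An [ecdf_vector()].
#' @export
#' @examples
#' S <- trajectory_set(c(0, 1), matrix(c(0, 1), 2, 1))
#' St <- trajectory_set(c(0, 1), matrix(c(0, 2), 2, 1))
#' pairwise_ecdf_trajectories(S, St, radius_bins(c(0.5, 1.5, 2.5)))$y
pairwise_ecdf_trajectories <- function(S, S_tilde, bins, norm = "L2",
                                       components = NULL) {
  stopifnot(inherits(S, "trajectory_set"), inherits(S_tilde, "trajectory_set"))
  A <- S$states; B <- S_tilde$states
  if (!is.null(components)) {
    A <- A[, components, drop = FALSE]
    B <- B[, components, drop = FALSE]
  }
  if (ncol(A) != ncol(B)) {
    stop_cil("trajectories have mismatched state dimensions",
             "cil_validation_error")
  }
  d <- cross_distances_(A, B, norm)
  ecdf_vector(ecdf_counts_(d, bins$R), bins, source = "trajectory-pair")
}

# all pairwise distances between rows of A and rows of B
cross_distances_ <- function(A, B, norm = "L2") {
  if (norm == "L2") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    return(sqrt(pmax(d2, 0)))
  }
  n <- nrow(A); m <- nrow(B)
  d <- matrix(0, n, m)
  for (k in seq_len(ncol(A))) {
    dk <- abs(outer(A[, k], B[, k], "-"))
    d <- if (norm == "L1") d + dk else pmax(d, dk)
  }
  if (!norm %in% c("L1", "Linf")) {
    stop_cil(sprintf("unknown norm '%s'", norm), "cil_validation_error")
  }
  d
}

#' Distance between two spatial patterns
#'
#' Grid-weighted discrete norm of the difference of two patterns on the same
#' grid: for cell volume `h`, `L2` is \eqn{(h \sum (p_1-p_2)^2)^{1/2}}, `L1`
#' is \eqn{h \sum |p_1-p_2|}, `Linf` the maximum absolute difference.
#'
#' @param p1,p2 numeric arrays of identical shape.
#' @param metric `"L2"` (default), `"L1"` or `"Linf"`.
#' @param cell_volume grid cell volume (default 1, i.e. plain vector norms).
#' @return Non-negative scalar; zero iff the patterns coincide.
#' @export
pattern_distance <- function(p1, p2, metric = "L2", cell_volume = 1) {
  shp <- function(p) if (is.null(dim(p))) length(p) else dim(p)
  if (!identical(shp(p1), shp(p2))) {
    stop_cil("patterns have mismatched shapes", "cil_validation_error")
  }
  d <- p1 - p2
  switch(metric,
         L2 = sqrt(cell_volume * sum(d^2)),
         L1 = cell_volume * sum(abs(d)),
         Linf = max(abs(d)),
         stop_cil(sprintf("unknown metric '%s'", metric),
                  "cil_validation_error"))
}

#' Distance sample between two pattern sets
#'
#' All cross distances between members of two pattern lists (or all unordered
#' within-set distances if `set2` is `NULL`).
#'
#' @param set1,set2 lists of patterns (or [pattern_ensemble()] objects).
#' @param metric see [pattern_distance()].
#' @return Numeric vector of distances.
#' @export
pattern_cross_distances <- function(set1, set2 = NULL, metric = "L2") {
  if (inherits(set1, "pattern_ensemble")) set1 <- set1$patterns
  within <- is.null(set2)
  if (!within && inherits(set2, "pattern_ensemble")) set2 <- set2$patterns
  if (within) {
    n <- length(set1)
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    return(vapply(seq_len(nrow(pairs)), function(r) {
      pattern_distance(set1[[pairs[r, 1]]], set1[[pairs[r, 2]]], metric)
    }, numeric(1)))
  }
  as.vector(vapply(set2, function(q) {
    vapply(set1, function(p) pattern_distance(p, q, metric), numeric(1))
  }, numeric(length(set1))))
}

#' eCDF vector of a distance sample
#'
#' Component k is the fraction of sampled distances strictly below the k-th
#' bin radius: \eqn{y_k = n^{-1} \#\{i : d_i < R_k\}}. Ties at a bin edge
#' count as outside the bin.
#'
#' @param d non-negative numeric vector of distances (non-empty).
#' @param bins a [radius_bins()].
#' @return An [ecdf_vector()].
#' @export
ecdf_patterns <- function(d, bins) {
  if (length(d) == 0) {
    stop_cil("empty distance sample", "cil_validation_error")
  }
  check_finite(d, "distances")
  ecdf_vector(ecdf_counts_(d, bins$R), bins, source = "pattern-subsets")
}

#' Place bin radii at quantiles of training distances
#'
#' Default bin-selection rule: `M` equally spaced quantiles of the pooled
#' training distances, strictly inside (0, max distance]. Duplicate quantiles
#' (possible for heavily tied samples) are collapsed and the reduced `M` is
#' reported via a warning.
#'
#' @param training_distances non-empty numeric vector of distances.
#' @param M requested number of bins, >= 2.
#' @param probs optional explicit quantile levels (length `M`).
#' @return A [radius_bins()].
#' @export
select_radii <- function(training_distances, M = 10, probs = NULL) {
  d <- training_distances
  if (length(d) == 0 || M < 2) {
    stop_cil("need non-empty distances and M >= 2", "cil_validation_error")
  }
  if (length(unique(d)) < M) {
    stop_cil("fewer than M distinct distances: bins degenerate",
             "cil_bins_degenerate_error")
  }
  probs <- probs %||% seq_len(M) / (M + 1)
  R <- unname(quantile(d, probs = probs, type = 7))
  R <- R[R > 0]
  Ru <- unique(R)
  if (length(Ru) < length(R) || length(Ru) < M) {
    warning(sprintf("collapsed duplicate bin radii: M reduced from %d to %d",
                    M, length(Ru)))
  }
  if (length(Ru) < 2) {
    stop_cil("degenerate training distances: cannot place bins",
             "cil_bins_degenerate_error")
  }
  radius_bins(Ru)
}
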