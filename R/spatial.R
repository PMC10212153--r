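# Moran's I test for spatial autocorrelation of per-station nocturnality.

#' Build a spatial weight matrix over stations
#'
#' Default scheme: inverse-distance weights `w_ij = 1/d_ij` (zero diagonal),
#' optionally row-standardized so each row sums to one. A k-nearest-neighbour
#' scheme (`w_ij = 1` for the k nearest stations) is available by
#' configuration.
#'
#' @param stations data frame with `station_id`, `x`, `y` (planar meters);
#'   at least 3 stations with distinct coordinates.
#' @param scheme `"inverse_distance"` or `"knn"`.
#' @param k number of neighbours for `"knn"`.
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return object of class `spatial_weights`: `w` (n x n matrix with station
#'   ids as dimnames), `scheme`, `row_standardized`.
#' @export
build_weights <- function(stations, scheme = c("inverse_distance", "knn"),
                          k = 4, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(stations) >= 3, all(c("x", "y") %in% names(stations)))
  n <- nrow(stations)
  d <- as.matrix(stats::dist(stations[, c("x", "y")]))
  if (any(d[upper.tri(d)] == 0)) {
    stop("build_weights: coincident stations (zero pairwise distance)")
  }
  w <- switch(scheme,
              inverse_distance = 1 / d,
              knn = {
                m <- matrix(0, n, n)
                for (i in seq_len(n)) {
                  nb <- order(d[i, ])[2:(k + 1L)]
                  m[i, nb] <- 1
                }
                m
              })
  diag(w) <- 0
  rs <- rowSums(w)
  if (any(rs == 0)) warning("build_weights: station(s) with all-zero weights")
  if (row_standardize) w <- w / ifelse(rs > 0, rs, 1)
  ids <- if ("station_id" %in% names(stations)) {
    as.character(stations$station_id)
  } else {
    as.character(seq_len(n))
  }
  dimnames(w) <- list(ids, ids)
  structure(list(w = w, scheme = scheme, row_standardized = row_standardize),
            class = "spatial_weights")
}

# the raw statistic: I = (n/W) sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#                     sum_i (x_i - xbar)^2
moran_stat <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of station values under a spatial weight
#' matrix, with a two-sided permutation p-value: the rank of the observed
#' statistic's deviation from its null expectation `-1/(n-1)` among values
#' recomputed under random permutations of the station labels.
#'
#' @param values numeric vector of per-station values (e.g. mean
#'   nocturnality), aligned with the weight matrix; must not be constant.
#' @param weights a [build_weights()] object (or bare matrix).
#' @param n_permutations default 999.
#' @param seed optional RNG seed for reproducible p-values.
#' @return object of class `moran_result`: `I`, `expected_I`, `p_value`,
#'   `n`, `n_permutations`, `scheme`.
#' @export
morans_i <- function(values, weights, n_permutations = 999, seed = NULL) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else weights
  n <- length(values)
  stopifnot(n >= 3, nrow(w) == n, ncol(w) == n)
  if (stats::sd(values) == 0) stop("morans_i: constant values (zero variance)")
  if (!is.null(seed)) set.seed(seed)
  I_obs <- moran_stat(values, w)
  e_I <- -1 / (n - 1)
  dev_obs <- abs(I_obs - e_I)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    I_b <- moran_stat(values[sample.int(n)], w)
    if (abs(I_b - e_I) >= dev_obs) exceed <- exceed + 1L
  }
  structure(list(I = I_obs, expected_I = e_I,
                 p_value = (1 + exceed) / (n_permutations + 1),
                 n = n, n_permutations = n_permutations,
                 scheme = if (inherits(weights, "spatial_weights"))
                   weights$scheme else "matrix"),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), permutation p = %.4f (%d permutations, n = %d)\n",
              x$I, x$expected_I, x$p_value, x$n_permutations, x$n))
  invisible(x)
}
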