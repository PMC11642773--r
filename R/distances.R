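# Configuration distances: periodic torsion RMS, plain RMS for the distance
# blocks, and the max-normalized weighted combination.

#' Distance component weights
#'
#' Weights for the torsion, CA-distance and H-bond-distance components of
#' the combined configuration distance. They must be nonnegative and sum
#' to one.
#'
#' @param w_theta,w_C,w_H nonnegative weights summing to 1 (within 1e-12).
#' @return an object of class `distance_weights` (named numeric length 3).
#' @export
distance_weights <- function(w_theta, w_C, w_H) {
  w <- c(theta = w_theta, C = w_C, H = w_H)
  if (any(w < 0)) stop("distance weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-12) stop("distance weights must sum to 1")
  structure(w, class = "distance_weights")
}

#' Periodic torsion distance between two configurations
#'
#' Root-mean-square of per-angle minimal circular differences: each angle
#' contributes \eqn{180 - ||\Delta| - 180|} degrees, the shortest arc
#' between the two torsions. Inputs are radians; the result is reported in
#' degrees (the unit cancels after max-normalization in the combined
#' distance).
#'
#' @param theta_i,theta_j equal-length torsion vectors in radians.
#' @return scalar distance in degrees.
#' @export
torsion_distance <- function(theta_i, theta_j) {
  if (length(theta_i) != length(theta_j))
    stop("torsion vectors must have equal length")
  if (!length(theta_i)) stop("torsion vectors must be non-empty")
  d <- abs(rad2deg(theta_i) - rad2deg(theta_j)) %% 360
  m <- 180 - abs(d - 180)
  sqrt(mean(m^2))
}

#' RMS distance between two feature vectors
#'
#' Root-mean-square of elementwise differences; used identically for the
#' CA-distance and H-bond-distance blocks.
#'
#' @param x_i,x_j equal-length numeric vectors.
#' @return scalar RMS distance.
#' @export
rms_feature_distance <- function(x_i, x_j) {
  if (length(x_i) != length(x_j))
    stop("feature vectors must have equal length")
  if (!length(x_i)) stop("feature vectors must be non-empty")
  sqrt(mean((x_i - x_j)^2))
}

#' Pairwise periodic torsion distance matrix
#'
#' @param theta frames x n_torsions matrix of angles in radians.
#' @return symmetric matrix of torsion distances in degrees.
#' @export
torsion_distance_matrix <- function(theta) {
  theta <- as.matrix(theta)
  n <- nrow(theta); k <- ncol(theta)
  deg <- rad2deg(theta)
  acc <- matrix(0, n, n)
  for (j in seq_len(k)) {
    d <- abs(outer(deg[, j], deg[, j], "-")) %% 360
    m <- 180 - abs(d - 180)
    acc <- acc + m * m
  }
  out <- sqrt(acc / k)
  diag(out) <- 0
  out
}

#' Pairwise RMS feature distance matrix
#'
#' @param x frames x n_features matrix.
#' @return symmetric matrix of RMS distances.
#' @export
feature_distance_matrix <- function(x) {
  x <- as.matrix(x)
  out <- as.matrix(stats::dist(x)) / sqrt(ncol(x))
  dimnames(out) <- NULL
  out
}

#' Combine component distance matrices
#'
#' Each component is divided by its maximum entry over the full matrix and
#' the normalized components are weighted-summed. A component whose maximum
#' is zero (a constant feature block) contributes zero. The normalizers are
#' recorded so new frames can be placed on the same scale.
#'
#' @param D_theta,D_C,D_H symmetric nonnegative matrices with zero diagonal.
#' @param w a [distance_weights()] object.
#' @return object of class `distance_matrices`: list with the combined `D`,
#'   the three components, `normalizers`, and `weights`.
#' @export
combine_distances <- function(D_theta, D_C, D_H, w) {
  stopifnot(inherits(w, "distance_weights"))
  dims <- list(dim(D_theta), dim(D_C), dim(D_H))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("component matrices must have identical shape")
  comps <- list(theta = D_theta, C = D_C, H = D_H)
  for (nm in names(comps)) {
    if (any(comps[[nm]] < 0)) stop("negative entries in D_", nm)
  }
  normalizers <- vapply(comps, max, numeric(1))
  D <- matrix(0, nrow(D_theta), ncol(D_theta))
  for (nm in names(comps)) {
    if (normalizers[[nm]] > 0)
      D <- D + unclass(w)[[nm]] * comps[[nm]] / normalizers[[nm]]
  }
  structure(list(D = D, D_theta = D_theta, D_C = D_C, D_H = D_H,
                 normalizers = normalizers, weights = w),
            class = "distance_matrices")
}

#' Pairwise combined distances of a feature set
#'
#' Convenience wrapper building the three component matrices from a
#' [frame_features()] object and combining them with [combine_distances()].
#'
#' @param features a `frame_features` object.
#' @param weights a [distance_weights()] object.
#' @return a `distance_matrices` object.
#' @export
frame_distances <- function(features, weights) {
  combine_distances(torsion_distance_matrix(features$theta),
                    feature_distance_matrix(features$ca_dist),
                    feature_distance_matrix(features$hbond_dist),
                    weights)
}

# Combined distance from every frame in `features` to every row of the
# medoid feature blocks, using frozen normalizers: places out-of-sample
# frames on the scale of the clustered set.
cross_distances <- function(features, med_theta, med_ca, med_hb,
                            normalizers, w) {
  n <- n_frames(features); m <- nrow(med_theta)
  Dth <- matrix(0, n, m); Dca <- matrix(0, n, m); Dhb <- matrix(0, n, m)
  deg <- rad2deg(features$theta); mdeg <- rad2deg(med_theta)
  for (j in seq_len(m)) {
    d <- abs(sweep(deg, 2L, mdeg[j, ], "-")) %% 360
    Dth[, j] <- sqrt(rowMeans((180 - abs(d - 180))^2))
    Dca[, j] <- sqrt(rowMeans(sweep(features$ca_dist, 2L, med_ca[j, ], "-")^2))
    Dhb[, j] <- sqrt(rowMeans(sweep(features$hbond_dist, 2L, med_hb[j, ], "-")^2))
  }
  w <- unclass(w)
  D <- matrix(0, n, m)
  if (normalizers[["theta"]] > 0) D <- D + w[["theta"]] * Dth / normalizers[["theta"]]
  if (normalizers[["C"]] > 0) D <- D + w[["C"]] * Dca / normalizers[["C"]]
  if (normalizers[["H"]] > 0) D <- D + w[["H"]] * Dhb / normalizers[["H"]]
  D
}
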