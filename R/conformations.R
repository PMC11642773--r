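# Two-stage clustering of configurations into intracellular-pocket
# conformations: complete-linkage agglomeration under the combined distance,
# then spectral grouping of cluster medoids under a Gaussian similarity of
# their superposed RMSDs.

#' Clustering hyperparameters
#'
#' @param weights a [distance_weights()] object.
#' @param H number of hierarchical clusters (>= 2).
#' @param delta Gaussian similarity bandwidth in Angstrom (> 0).
#' @param C number of conformations, with `2 <= C <= H - 1`.
#' @return an object of class `hyperparameters`.
#' @export
hyperparameters <- function(weights, H, delta, C) {
  stopifnot(inherits(weights, "distance_weights"))
  H <- as.integer(H); C <- as.integer(C)
  if (H < 2L) stop("H must be at least 2")
  if (delta <= 0) stop("delta must be positive")
  if (C < 2L || C > H - 1L) stop("C must satisfy 2 <= C <= H - 1")
  structure(list(weights = weights, H = H, delta = delta, C = C),
            class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  w <- unclass(x$weights)
  cat(sprintf("Hyperparameters: w = (%.3g, %.3g, %.3g), H = %d, delta = %g, C = %d\n",
              w[["theta"]], w[["C"]], w[["H"]], x$H, x$delta, x$C))
  invisible(x)
}

#' Complete-linkage hierarchical clustering of frames
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param H number of clusters to cut (<= number of frames).
#' @return integer vector of cluster labels in `1..H`.
#' @export
hierarchical_cluster <- function(D, H) {
  n <- nrow(D)
  if (H > n) stop("H (", H, ") exceeds the number of frames (", n, ")")
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  stats::cutree(hc, k = H)
}

#' Cluster medoids under a distance matrix
#'
#' For each cluster, the member minimizing the summed distance to all other
#' members; ties broken by the lowest frame index.
#'
#' @param labels integer cluster labels per frame.
#' @param D symmetric distance matrix over the same frames.
#' @return integer vector: frame index of the medoid of each cluster, in
#'   ascending cluster-id order.
#' @export
compute_medoids <- function(labels, D) {
  ids <- sort(unique(labels))
  vapply(ids, function(cl) {
    rows <- which(labels == cl)
    sums <- rowSums(D[rows, rows, drop = FALSE])
    rows[which.min(sums)]  # which.min returns the first (lowest-index) tie
  }, integer(1))
}

#' Pairwise RMSD matrix of medoid structures
#'
#' Minimal root-mean-square deviation after optimal rigid-body (Kabsch)
#' superposition of each pair. Superposition uses [bio3d::fit.xyz()]; the
#' deviation itself is computed at full precision from the superposed
#' coordinates.
#'
#' @param coords matrix with one row per medoid, xyz-interleaved coordinates
#'   of a shared ordered atom selection.
#' @param fit superpose before computing the RMSD (default `TRUE`).
#' @return symmetric matrix of RMSDs in Angstrom.
#' @export
centroid_rmsd_matrix <- function(coords, fit = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) %% 3L != 0L)
    stop("coords must have 3 columns per atom")
  h <- nrow(coords); k <- ncol(coords)
  out <- matrix(0, h, h)
  if (h < 2L) return(out)
  for (i in seq_len(h - 1L)) {
    for (j in (i + 1L):h) {
      b <- coords[j, ]
      if (fit)
        b <- drop(bio3d::fit.xyz(fixed = coords[i, ],
                                 mobile = matrix(b, 1L),
                                 fixed.inds = seq_len(k),
                                 mobile.inds = seq_len(k)))
      out[i, j] <- out[j, i] <- sqrt(sum((coords[i, ] - b)^2) / (k / 3L))
    }
  }
  out
}

#' Gaussian similarity of an RMSD matrix
#'
#' \eqn{S = \exp(-D^2 / (2\delta^2))} elementwise.
#'
#' @param D_rmsd symmetric nonnegative matrix (Angstrom).
#' @param delta bandwidth in Angstrom (> 0).
#' @return similarity matrix with unit diagonal and entries in (0, 1].
#' @export
gaussian_similarity <- function(D_rmsd, delta) {
  if (delta <= 0) stop("delta must be positive")
  if (any(D_rmsd < 0)) stop("D_rmsd must be nonnegative")
  exp(-D_rmsd^2 / (2 * delta^2))
}

#' Spectral grouping of medoids with QR-based assignment
#'
#' Embeds the similarity graph with the C leading eigenvectors of the
#' normalized graph Laplacian (random-walk scaling) and assigns clusters by
#' the deterministic pivoted-QR strategy: a column-pivoted QR factorization
#' of the transposed embedding picks C representative medoids, and each
#' medoid joins the representative with which it has the largest polar-
#' rotated overlap. No k-means, hence no random initialization.
#'
#' @param S symmetric similarity matrix, unit diagonal, entries in (0, 1].
#' @param C number of conformations (< number of medoids).
#' @return integer vector of conformation labels in `1..C` (every id used
#'   at least once, or a `confeff_empty_conformation` error).
#' @export
spectral_conformations <- function(S, C) {
  h <- nrow(S)
  if (C >= h) stop("C must be smaller than the number of medoids")
  d <- rowSums(S)
  dm <- 1 / sqrt(d)
  L <- diag(h) - (S * outer(dm, dm))
  eg <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- eg$vectors[, h - seq_len(C) + 1L, drop = FALSE]  # C smallest eigenvalues
  U <- U * dm  # random-walk normalization of the embedding
  piv <- qr(t(U), LAPACK = TRUE)$pivot[seq_len(C)]
  sv <- svd(t(U[piv, , drop = FALSE]))
  rot <- sv$u %*% t(sv$v)
  labels <- max.col(abs(U %*% rot), ties.method = "first")
  if (length(unique(labels)) < C)
    confeff_error("spectral assignment left a conformation empty",
                  "confeff_empty_conformation")
  labels
}

#' Per-ligand conformation fractions
#'
#' \eqn{f_{l,c}}: the fraction of ligand l's frames labeled conformation c,
#' pooling replicas. Rows sum to one.
#'
#' @param conf_labels integer conformation labels per frame.
#' @param ligand ligand label per frame.
#' @param C total number of conformations (default `max(conf_labels)`).
#' @return matrix (ligand x conformation) of fractions, rows summing to 1.
#' @export
compute_fractions <- function(conf_labels, ligand, C = max(conf_labels)) {
  ligs <- unique(ligand)
  counts <- table(factor(ligand, levels = ligs),
                  factor(conf_labels, levels = seq_len(C)))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("ligand with zero frames: ",
                          paste(ligs[tot == 0], collapse = ", "))
  f <- matrix(counts, nrow = nrow(counts)) / tot  # plain numeric matrix
  dimnames(f) <- list(ligs, paste0("conf_", seq_len(C)))
  f
}

#' Fit the two-stage conformation model
#'
#' Clusters a (possibly strided) subsample of frames with complete linkage
#' under the combined distance, groups the cluster medoids into C
#' conformations spectrally, and then labels every frame: subsampled frames
#' keep their agglomerative cluster, frames outside the subsample join the
#' hierarchical cluster of their nearest medoid under the combined distance
#' with the frozen normalizers. Conformation labels are always the
#' composition of the medoid grouping with the hierarchical labels.
#'
#' @param features a [frame_features()] object with coordinates (needed for
#'   the medoid RMSD stage).
#' @param hp a [hyperparameters()] object.
#' @param stride cluster every `stride`-th frame (default 1 = all frames).
#' @param subsample optional explicit frame indices to cluster (overrides
#'   `stride`).
#' @return an object of class `conformation_model`.
#' @export
conformation_model <- function(features, hp, stride = 1L, subsample = NULL) {
  stopifnot(inherits(features, "frame_features"), inherits(hp, "hyperparameters"))
  if (is.null(features$coords))
    stop("features must carry coordinates for the medoid RMSD stage")
  n <- n_frames(features)
  idx <- subsample %||% seq(1L, n, by = as.integer(stride))
  sub <- features[idx]
  dm <- frame_distances(sub, hp$weights)
  hc <- stats::hclust(stats::as.dist(dm$D), method = "complete")
  finish_conformation_model(features, hp, idx, dm, hc)
}

# Shared tail of conformation_model(), reused by the grid-search cache.
finish_conformation_model <- function(features, hp, idx, dm, hc,
                                      labs = NULL, med_local = NULL,
                                      D_rmsd = NULL) {
  if (is.null(labs)) labs <- stats::cutree(hc, k = hp$H)
  if (is.null(med_local)) med_local <- compute_medoids(labs, dm$D)
  medoid_index <- idx[med_local]
  if (is.null(D_rmsd))
    D_rmsd <- centroid_rmsd_matrix(features$coords[medoid_index, , drop = FALSE])
  S <- gaussian_similarity(D_rmsd, hp$delta)
  conf_of_cluster <- spectral_conformations(S, hp$C)

  hier_all <- integer(n_frames(features))
  hier_all[idx] <- labs
  rest <- setdiff(seq_len(n_frames(features)), idx)
  if (length(rest)) {
    Dx <- cross_distances(features[rest],
                          features$theta[medoid_index, , drop = FALSE],
                          features$ca_dist[medoid_index, , drop = FALSE],
                          features$hbond_dist[medoid_index, , drop = FALSE],
                          dm$normalizers, hp$weights)
    hier_all[rest] <- max.col(-Dx, ties.method = "first")
  }
  conf_labels <- conf_of_cluster[hier_all]
  fractions <- compute_fractions(conf_labels, features$ligand, hp$C)
  structure(list(hp = hp, subsample = idx, hier_labels = hier_all,
                 medoid_index = medoid_index, D_rmsd = D_rmsd, S_rmsd = S,
                 conf_of_cluster = conf_of_cluster, conf_labels = conf_labels,
                 fractions = fractions, normalizers = dm$normalizers,
                 ligands = rownames(fractions)),
            class = "conformation_model")
}

#' @export
print.conformation_model <- function(x, ...) {
  cat("Conformation model:", x$hp$C, "conformations from", x$hp$H,
      "hierarchical clusters\n")
  cat("  frames:", length(x$conf_labels), "(", length(x$subsample),
      "clustered )\n")
  cat("  occupancy range:",
      paste(sprintf("%.3f", range(x$fractions)), collapse = " - "), "\n")
  invisible(x)
}

#' Assign new frames to fitted conformations
#'
#' Nearest-medoid assignment under the combined distance with the model's
#' frozen normalizers, composed with the fitted medoid-to-conformation map.
#'
#' @param object a [conformation_model()].
#' @param features a [frame_features()] object with matching block widths.
#' @param what return `"conformation"` (default) or `"cluster"` labels.
#' @param model_features the feature set the model was fitted on; required
#'   to look up medoid feature rows (stored indices refer to it).
#' @return integer labels per frame of `features`.
#' @export
assign_frames <- function(object, features, model_features,
                          what = c("conformation", "cluster")) {
  what <- match.arg(what)
  mi <- object$medoid_index
  Dx <- cross_distances(features,
                        model_features$theta[mi, , drop = FALSE],
                        model_features$ca_dist[mi, , drop = FALSE],
                        model_features$hbond_dist[mi, , drop = FALSE],
                        object$normalizers, object$hp$weights)
  cl <- max.col(-Dx, ties.method = "first")
  if (what == "cluster") cl else object$conf_of_cluster[cl]
}
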