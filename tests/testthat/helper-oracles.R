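# Independent oracles and small fixture builders used across the suite.

# Brute-force medoid: scan every member as candidate.
brute_medoid <- function(labels, D) {
  vapply(sort(unique(labels)), function(cl) {
    rows <- which(labels == cl)
    best <- rows[1L]; best_sum <- Inf
    for (r in rows) {
      s <- sum(D[r, rows])
      if (s < best_sum) { best <- r; best_sum <- s }
    }
    best
  }, integer(1))
}

# Connected components of a logical adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Brute-force minimal RMSD over rigid rotations via quaternion
# parameterization (plus centering), independent of the Kabsch route.
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

quat_rmsd <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A)); B <- sweep(B, 2L, colMeans(B))
  obj <- function(q) sqrt(mean(rowSums((A %*% t(quat_rotation(q)) - B)^2)))
  best <- Inf
  set.seed(99)
  for (k in 1:40) {
    q0 <- rnorm(4)
    o <- optim(q0, obj, method = "BFGS", control = list(maxit = 500))
    best <- min(best, o$value)
  }
  best
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# Two well-separated Gaussian blobs in feature space, as frame features.
make_blob_features <- function(n_per = 25L, gap = 50, sd = 0.5, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per
  centers <- rbind(rep(0, 4), rep(gap, 4))
  lab <- rep(1:2, each = n_per)
  ca <- centers[lab, ] + matrix(rnorm(n * 4, 0, sd), n)
  ca <- abs(ca)
  theta <- matrix(rvonmises(n * 3, rep(c(-1, 1)[lab], 3), 200), n)
  hb <- matrix(5 + rnorm(n * 2, 0, 0.1), n)
  coords <- cbind(ca[, 1:2], matrix(0, n, 4)) + 1  # 2 pseudo-atoms
  frame_features(theta, ca, hb, ligand = rep("L1", n), coords = coords,
                 template = lab)
}

# A small all-atom-ish peptide frame for featurization tests: backbone
# N/CA/C plus CB/CG/CD side chains, helical-ish geometry with jitter.
make_peptide_atoms <- function(n_res = 6L, seed = 7L) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_res)) {
    base <- c(3.5 * r, 2 * sin(r), 2 * cos(r))
    at <- rbind(N = base + c(-1.2, 0.3, 0),
                CA = base,
                C = base + c(1.3, 0.4, 0.2),
                O = base + c(1.5, 1.6, 0.2),
                CB = base + c(0.2, -1.4, 0.5),
                CG = base + c(0.3, -2.2, 1.6),
                CD = base + c(1.2, -3.1, 1.9))
    at <- at + matrix(rnorm(length(at), 0, 0.05), nrow(at))
    rows[[r]] <- data.frame(elety = rownames(at), resno = r,
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

apply_rigid <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2L, t, "+")
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  atoms
}

# Match fitted conformation columns to planted templates by contingency
# majority, returning the reordered fraction matrix.
match_fractions <- function(fractions, conf_labels, template) {
  tab <- table(factor(conf_labels, levels = seq_len(ncol(fractions))),
               template)
  perm <- apply(tab, 1L, which.max)
  fractions[, order(perm), drop = FALSE]
}

# Small oracle-adjacent grid used by the desk-scale recovery studies.
desk_grid <- function(C = 5:6, H = c(10L, 14L)) {
  efficacy_grid(weights = list(distance_weights(1/3, 1/3, 1/3),
                               distance_weights(0.25, 0.25, 0.5)),
                H = H, delta = 2, C = C)
}

# Exact integral of a step density over a domain: per-bin overlap length
# times bin density. Independent of the evaluator path.
step_integral <- function(d, domain) {
  lo <- pmax(d$breaks[-length(d$breaks)], domain[1L])
  hi <- pmin(d$breaks[-1L], domain[2L])
  sum(pmax(hi - lo, 0) * d$density)
}
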