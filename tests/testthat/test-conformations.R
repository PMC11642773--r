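# Two-stage clustering: complete-linkage recovery, medoids, superposed
# RMSD, Gaussian similarity, spectral grouping, fractions.

test_that("complete linkage recovers well-separated blobs", {
  feats <- make_blob_features(n_per = 40)
  dm <- frame_distances(feats, distance_weights(1/3, 1/3, 1/3))
  labs <- hierarchical_cluster(dm$D, 2)
  # oracle: blob membership (inter-blob distance ~100x intra)
  expect_equal(length(unique(labs)), 2L)
  expect_true(all(table(labs, feats$template) %in% c(0L, 40L)))

  # cutting at n frames puts every frame alone
  labs_n <- hierarchical_cluster(dm$D[1:10, 1:10], 10)
  expect_equal(sort(unique(labs_n)), 1:10)

  # duplicate frames merge first at every coarser cut
  D <- dm$D[1:8, 1:8]
  D[2, 5] <- D[5, 2] <- 0
  D[5, ] <- D[2, ]; D[, 5] <- D[, 2]; D[5, 5] <- 0
  for (H in 2:7) {
    l <- hierarchical_cluster(D, H)
    expect_equal(l[2], l[5])
  }
  expect_error(hierarchical_cluster(D, 9), "exceeds")
})

test_that("medoids minimize the summed within-cluster distance", {
  # three collinear points at pairwise distances (1, 2, 3): middle wins
  D3 <- rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0))
  expect_equal(compute_medoids(rep(1L, 3), D3), 2L)
  # singleton cluster returns its only member
  expect_equal(compute_medoids(c(1L, 2L, 2L), D3), c(1L, 2L))

  set.seed(31)
  n <- 60
  X <- matrix(rnorm(n * 3), n)
  D <- as.matrix(dist(X))
  labs <- sample(1:4, n, replace = TRUE)
  expect_equal(compute_medoids(labs, D), brute_medoid(labs, D))

  # exact duplicates of the minimal-sum frame: lowest index wins
  Ddup <- as.matrix(dist(rbind(X[1, ], X[1, ], X[1, ] + 5)))
  expect_equal(compute_medoids(rep(1L, 3), Ddup), 1L)
})

test_that("centroid RMSD is superposition-invariant and matches a quaternion oracle", {
  set.seed(17)
  A <- matrix(rnorm(12), 4)
  R <- random_rotation(3)
  B <- sweep(A %*% t(R), 2, c(5, -2, 9), "+")
  coords <- rbind(as.vector(t(A)), as.vector(t(B)))
  M <- centroid_rmsd_matrix(coords)
  expect_equal(M[1, 1], 0)
  expect_lt(M[1, 2], 1e-9)  # rigid motion is removed by superposition

  # displaced copy: compare against brute-force quaternion minimization
  Cset <- A; Cset[2, ] <- Cset[2, ] + c(1, 0, 0)
  M2 <- centroid_rmsd_matrix(rbind(as.vector(t(A)), as.vector(t(Cset))))
  expect_equal(M2[1, 2], quat_rmsd(A, Cset), tolerance = 1e-6)
})

test_that("Gaussian similarity follows the closed form", {
  expect_equal(gaussian_similarity(matrix(0, 1, 1), 2)[1, 1], 1)
  d <- 2 * sqrt(2)
  expect_equal(gaussian_similarity(matrix(d, 1, 1), 2)[1, 1], exp(-1))
  expect_gt(gaussian_similarity(matrix(1, 1, 1), 2)[1, 1],
            gaussian_similarity(matrix(2, 1, 1), 2)[1, 1])
  expect_error(gaussian_similarity(matrix(0, 1, 1), 0), "positive")
})

test_that("spectral grouping recovers similarity blocks deterministically", {
  set.seed(23)
  sizes <- c(4, 5, 3)
  block_of <- rep(1:3, sizes)
  n <- sum(sizes)
  S <- matrix(exp(-50), n, n)
  for (b in 1:3) {
    i <- which(block_of == b)
    S[i, i] <- 0.95 + 0.05 * diag(length(i))
  }
  S <- (S + t(S)) / 2; diag(S) <- 1
  labs <- spectral_conformations(S, 3)
  # oracle: connected components of the thresholded graph
  comp <- connected_components(S > 0.5)
  expect_equal(length(unique(labs)), 3L)
  expect_true(all(apply(table(labs, comp) > 0, 1, sum) == 1))

  # permuting the medoids permutes labels consistently (same partition)
  perm <- sample(n)
  labs_p <- spectral_conformations(S[perm, perm], 3)
  expect_equal(outer(labs_p, labs_p, "=="),
               outer(labs[perm], labs[perm], "=="))

  expect_error(spectral_conformations(S, n), "smaller")
  expect_error(hyperparameters(distance_weights(1, 0, 0), H = 5, delta = 1,
                               C = 5), "C must satisfy")
})

test_that("fractions count frames per ligand and pool replicas", {
  lab <- c(rep(3L, 5), rep(1L, 3), rep(2L, 7))
  lig <- c(rep("A", 5), rep("B", 10))
  f <- compute_fractions(lab, lig, C = 3)
  expect_equal(unname(f["A", ]), c(0, 0, 1))
  expect_equal(unname(f["B", ]), c(0.3, 0.7, 0))
  expect_equal(rowSums(f), c(A = 1, B = 1))
})

test_that("conformation labels are the composition of the two stages", {
  st <- synthetic_study(n_templates = 3, n_ligands = 5,
                        n_frames_per_ligand = 120, n_replicas = 2, seed = 6)
  hp <- hyperparameters(distance_weights(1/3, 1/3, 1/3), H = 6, delta = 2,
                        C = 3)
  cm <- conformation_model(st$features, hp, stride = 3)
  expect_identical(cm$conf_labels, cm$conf_of_cluster[cm$hier_labels])
  expect_equal(sort(unique(cm$conf_labels)), 1:3)
  expect_equal(diag(cm$S_rmsd), rep(1, hp$H))
  expect_true(all(cm$S_rmsd > 0 & cm$S_rmsd <= 1))
  expect_equal(rowSums(cm$fractions), rep(1, 5), ignore_attr = TRUE)
  # determinism of the whole stage
  cm2 <- conformation_model(st$features, hp, stride = 3)
  expect_identical(cm$conf_labels, cm2$conf_labels)

  # out-of-sample assignment agrees with the fitted labels on seen frames
  re <- assign_frames(cm, st$features[1:50], st$features)
  disagree <- mean(re != cm$conf_labels[1:50])
  expect_lt(disagree, 0.05)
})
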