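# Featurization: dihedrals, pair enumeration, H-bond admission, and
# rigid-body invariance of all three blocks.

test_that("dihedral angle matches its geometric definition", {
  p2 <- c(0, 0, 0); p3 <- c(0, 0, 1)
  # cis (eclipsed, coplanar) is zero; trans is half a turn
  expect_equal(compute_dihedral(c(1, 0, 0), p2, p3, c(1, 0, 1)), 0)
  expect_equal(abs(compute_dihedral(c(1, 0, 0), p2, p3, c(-1, 0, 1))), pi)
  # constructed twist about the p2-p3 axis: the rotation itself is the oracle
  for (g in c(-2.5, -1.2, -0.3, 0.4, 1.7, 2.9)) {
    expect_equal(compute_dihedral(c(1, 0, 0), p2, p3, c(cos(g), sin(g), 1)),
                 g, tolerance = 1e-12)
  }
  expect_error(compute_dihedral(c(0, 0, -1), p2, p3, c(1, 0, 1)),
               "collinear")
})

test_that("CA pair enumeration enforces the sequence-separation rule", {
  sp <- feature_spec(data.frame(resno = 10, angle = "phi"),
                     ca_residues = c(10, 11, 14))
  pairs <- enumerate_ca_pairs(sp)
  expect_equal(unname(pairs), rbind(c(10, 14), c(11, 14)))

  single <- feature_spec(data.frame(resno = 1, angle = "phi"),
                         ca_residues = 5)
  expect_equal(nrow(enumerate_ca_pairs(single)), 0L)

  # the bundled receptor spec: 22 positions, none adjacent -> choose(22, 2)
  mor <- read_feature_spec(system.file("extdata", "mor_feature_spec.yaml",
                                       package = "confeff"))
  expect_length(mor$ca_residues, 22L)
  expect_equal(nrow(enumerate_ca_pairs(mor)), choose(22, 2))
  # brute-force oracle over all position pairs
  brute <- sum(outer(mor$ca_residues, mor$ca_residues,
                     function(a, b) abs(a - b) >= 2)) / 2
  expect_equal(nrow(enumerate_ca_pairs(mor)), brute)
})

test_that("H-bond pairs are admitted by the inclusive reference cutoff", {
  ref <- data.frame(elety = c("ND2", "OD1", "NE2", "OE1", "NZ", "OG"),
                    resno = 1:6,
                    x = c(0, 7.99, 8.01, 3, 20, 14),
                    y = 0, z = 0, stringsAsFactors = FALSE)
  cand <- data.frame(donor_resno = c(1, 1, 1, 5, 5),
                     donor_atom = c("ND2", "ND2", "ND2", "NZ", "NZ"),
                     acceptor_resno = c(2, 3, 4, 4, 6),
                     acceptor_atom = c("OD1", "NE2", "OE1", "OE1", "OG"),
                     stringsAsFactors = FALSE)
  adm <- select_hbond_pairs(ref, cand, cutoff = 8.0)
  # 7.99 in, 8.01 out; remaining distances 3, 17, 6 -> 3 of 5 admitted
  expect_equal(nrow(adm), 3L)
  expect_true(all(adm$ref_dist <= 8.0))
  expect_false(any(adm$acceptor_resno == 3))

  expect_error(select_hbond_pairs(ref,
      data.frame(donor_resno = 9, donor_atom = "ND2",
                 acceptor_resno = 2, acceptor_atom = "OD1")),
      "lacks atom ND2 of residue 9")
})

test_that("spec compilation drops absent angles and rejects empty blocks", {
  atoms <- make_peptide_atoms(6)
  # residue 3 loses its CG: chi2 (and chi1 gamma atom) unavailable there
  atoms <- atoms[!(atoms$resno == 3 & atoms$elety == "CG"), ]
  sp <- feature_spec(expand.grid(resno = 2:5,
                                 angle = c("phi", "psi", "chi1", "chi2"),
                                 stringsAsFactors = FALSE),
                     ca_residues = c(1, 3, 6),
                     hbond_candidates = data.frame(
                       donor_resno = 1, donor_atom = "N",
                       acceptor_resno = 2, acceptor_atom = "O"))
  cs <- compile_feature_spec(sp, atoms)
  # 4 residues x 4 angles minus the two chi angles of residue 3
  expect_equal(cs$n_theta, 14L)
  expect_false(any(grepl("chi[12]_3", cs$torsion_labels)))
  expect_equal(cs$n_ca, 3L)

  far <- sp
  far$hbond_candidates$acceptor_resno <- 6  # beyond 8 A in this geometry
  expect_error(compile_feature_spec(far, atoms), "N_H must be >= 1")
})

test_that("feature vectors are invariant under rigid-body motion", {
  atoms <- make_peptide_atoms(6)
  sp <- feature_spec(expand.grid(resno = 2:5, angle = c("phi", "psi", "chi1"),
                                 stringsAsFactors = FALSE),
                     ca_residues = c(1, 3, 6),
                     hbond_candidates = data.frame(
                       donor_resno = 1, donor_atom = "N",
                       acceptor_resno = 2, acceptor_atom = "O"))
  cs <- compile_feature_spec(sp, atoms)
  f0 <- featurize_frame(atoms, cs)

  # a CA pair placed on a 3-4-5 triangle
  at2 <- atoms
  at2[at2$resno == 1 & at2$elety == "CA", c("x", "y", "z")] <- c(0, 0, 0)
  at2[at2$resno == 3 & at2$elety == "CA", c("x", "y", "z")] <- c(3, 4, 0)
  f2 <- featurize_frame(at2, cs)
  expect_equal(unname(f2$ca_dist[["ca_1_3"]]), 5)

  expect_identical(featurize_frame(atoms, cs), f0)  # determinism

  for (s in 1:3) {
    R <- random_rotation(s)
    moved <- apply_rigid(atoms, R, c(10 * s, -3, 7))
    fm <- featurize_frame(moved, cs)
    expect_equal(fm$theta, f0$theta, tolerance = 1e-9)
    expect_equal(fm$ca_dist, f0$ca_dist, tolerance = 1e-9)
    expect_equal(fm$hbond_dist, f0$hbond_dist, tolerance = 1e-9)
  }
})
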