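# Featurization: turn per-frame atomic coordinates into the three feature
# blocks (torsions, CA pair distances, H-bond donor-acceptor distances)
# under a declarative feature specification.

#' Signed dihedral angle of four points
#'
#' Standard torsion about the p2-p3 axis: 0 for the cis (eclipsed) planar
#' arrangement, +/- pi for trans. The sign follows the usual right-hand
#' convention looking down the p2->p3 bond.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return angle in radians in \eqn{[-\pi, \pi)}.
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    confeff_error("dihedral undefined: three consecutive points are collinear",
                  "confeff_collinear")
  b2u <- b2 / sqrt(sum(b2^2))
  wrap_angle(atan2(sum(cross3(n1, n2) * b2u), sum(n1 * n2)))
}

#' Declarative feature specification
#'
#' Describes which torsions, alpha-carbon pairs and hydrogen-bond candidate
#' pairs make up the feature vectors. Compile it against a reference frame
#' with [compile_feature_spec()] before featurizing.
#'
#' @param torsions data.frame with columns `resno` and `angle`
#'   (one of `"phi"`, `"psi"`, `"chi1"`, `"chi2"`); one row per requested
#'   angle.
#' @param ca_residues integer vector of residue numbers whose alpha carbons
#'   define the distance block; residue numbers double as sequence positions.
#' @param hbond_candidates optional data.frame with columns `donor_resno`,
#'   `donor_atom`, `acceptor_resno`, `acceptor_atom`. If `NULL`, candidates
#'   are enumerated at compile time from `donor_atoms`/`acceptor_atoms`
#'   name sets over the reference frame.
#' @param hbond_cutoff admit candidate pairs at most this far apart
#'   (Angstrom) in the reference frame; the comparison is inclusive (`<=`).
#' @param min_sequence_separation CA pairs must be at least this many
#'   sequence positions apart (default 2: "at least one residue in between").
#' @param donor_atoms,acceptor_atoms atom-name sets used to enumerate H-bond
#'   candidates when `hbond_candidates` is `NULL`. The default polar-atom
#'   sets are a conventional reconstruction, not a curated list.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(torsions, ca_residues, hbond_candidates = NULL,
                         hbond_cutoff = 8.0, min_sequence_separation = 2L,
                         donor_atoms = c("N", "ND1", "ND2", "NE", "NE1",
                                         "NE2", "NH1", "NH2", "NZ", "OG",
                                         "OG1", "OH", "SG"),
                         acceptor_atoms = c("O", "OD1", "OD2", "OE1", "OE2",
                                            "OG", "OG1", "OH", "ND1", "NE2",
                                            "SD")) {
  stopifnot(is.data.frame(torsions), all(c("resno", "angle") %in% names(torsions)),
            hbond_cutoff > 0, min_sequence_separation >= 1)
  if (anyDuplicated(ca_residues))
    stop("`ca_residues` must be unique")
  bad <- setdiff(torsions$angle, c("phi", "psi", "chi1", "chi2"))
  if (length(bad))
    stop("unknown torsion angle name(s): ", paste(bad, collapse = ", "))
  structure(list(torsions = torsions,
                 ca_residues = as.integer(ca_residues),
                 hbond_candidates = hbond_candidates,
                 hbond_cutoff = hbond_cutoff,
                 min_sequence_separation = as.integer(min_sequence_separation),
                 donor_atoms = donor_atoms,
                 acceptor_atoms = acceptor_atoms),
            class = "feature_spec")
}

#' Enumerate admitted alpha-carbon pairs
#'
#' All unordered pairs of CA residues whose sequence positions differ by at
#' least `min_sequence_separation`, in canonical order (ascending by first
#' then second residue number).
#'
#' @param spec a [feature_spec()].
#' @return two-column integer matrix of residue numbers (possibly 0 rows).
#' @export
enumerate_ca_pairs <- function(spec) {
  res <- sort(spec$ca_residues)
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("res_i", "res_j")))
  if (length(res) < 2L) return(out)
  pr <- t(utils::combn(res, 2L))
  keep <- abs(pr[, 2L] - pr[, 1L]) >= spec$min_sequence_separation
  pr <- pr[keep, , drop = FALSE]
  pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  colnames(pr) <- c("res_i", "res_j")
  pr
}

# Atom quadruple patterns per torsion name. Offsets are residue offsets;
# alternatives for the distal atom are tried in order.
torsion_atom_patterns <- function(angle) {
  switch(angle,
    phi  = list(list(off = -1L, alt = "C"),  list(off = 0L, alt = "N"),
                list(off = 0L, alt = "CA"),  list(off = 0L, alt = "C")),
    psi  = list(list(off = 0L, alt = "N"),   list(off = 0L, alt = "CA"),
                list(off = 0L, alt = "C"),   list(off = 1L, alt = "N")),
    chi1 = list(list(off = 0L, alt = "N"),   list(off = 0L, alt = "CA"),
                list(off = 0L, alt = "CB"),
                list(off = 0L, alt = c("CG", "CG1", "OG", "OG1", "SG"))),
    chi2 = list(list(off = 0L, alt = "CA"),  list(off = 0L, alt = "CB"),
                list(off = 0L, alt = c("CG", "CG1")),
                list(off = 0L, alt = c("CD", "CD1", "OD1", "ND1", "SD"))),
    stop("unknown torsion angle: ", angle))
}

atom_index <- function(ref) {
  structure(seq_len(nrow(ref)), names = paste(ref$resno, ref$elety))
}

lookup_atom <- function(idx, resno, elety) {
  for (a in elety) {
    hit <- idx[paste(resno, a)]
    if (!is.na(hit)) return(unname(hit))
  }
  NA_integer_
}

#' Select admitted hydrogen-bond pairs against a reference frame
#'
#' Keeps candidate (donor, acceptor) pairs whose distance in the reference
#' frame is within the cutoff (inclusive). The admitted list is frozen into
#' the compiled spec and reused for every subsequent frame.
#'
#' @param reference atom data.frame with columns `elety`, `resno`, `x`, `y`,
#'   `z` for the reference frame.
#' @param candidates data.frame with columns `donor_resno`, `donor_atom`,
#'   `acceptor_resno`, `acceptor_atom`.
#' @param cutoff admission distance in Angstrom (default 8.0, inclusive).
#' @return `candidates` rows admitted, with the resolved atom row indices
#'   in columns `i` and `j` and the reference distance in `ref_dist`.
#' @export
select_hbond_pairs <- function(reference, candidates, cutoff = 8.0) {
  idx <- atom_index(reference)
  xyz <- as.matrix(reference[, c("x", "y", "z")])
  n <- nrow(candidates)
  i <- j <- integer(n)
  for (k in seq_len(n)) {
    i[k] <- lookup_atom(idx, candidates$donor_resno[k], candidates$donor_atom[k])
    if (is.na(i[k]))
      stop("reference frame lacks atom ", candidates$donor_atom[k],
           " of residue ", candidates$donor_resno[k])
    j[k] <- lookup_atom(idx, candidates$acceptor_resno[k], candidates$acceptor_atom[k])
    if (is.na(j[k]))
      stop("reference frame lacks atom ", candidates$acceptor_atom[k],
           " of residue ", candidates$acceptor_resno[k])
  }
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  keep <- d <= cutoff
  out <- candidates[keep, , drop = FALSE]
  out$i <- i[keep]; out$j <- j[keep]; out$ref_dist <- d[keep]
  rownames(out) <- NULL
  out
}

enumerate_hbond_candidates <- function(spec, reference) {
  res <- sort(unique(c(spec$torsions$resno, spec$ca_residues)))
  don <- reference[reference$resno %in% res &
                     reference$elety %in% spec$donor_atoms, , drop = FALSE]
  acc <- reference[reference$resno %in% res &
                     reference$elety %in% spec$acceptor_atoms, , drop = FALSE]
  if (!nrow(don) || !nrow(acc)) return(NULL)
  g <- expand.grid(d = seq_len(nrow(don)), a = seq_len(nrow(acc)))
  cand <- data.frame(donor_resno = don$resno[g$d], donor_atom = don$elety[g$d],
                     acceptor_resno = acc$resno[g$a], acceptor_atom = acc$elety[g$a],
                     stringsAsFactors = FALSE)
  # distinct residues, one direction per atom pair
  cand <- cand[cand$donor_resno != cand$acceptor_resno, , drop = FALSE]
  key <- apply(cand, 1L, function(r) paste(sort(c(paste(r[1], r[2]), paste(r[3], r[4]))),
                                           collapse = "|"))
  cand <- cand[!duplicated(key), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Compile a feature specification against a reference frame
#'
#' Resolves torsion atom quadruples (requested angles whose atoms are absent
#' are dropped, never imputed), enumerates admitted CA pairs, and freezes the
#' hydrogen-bond pair list by the reference-distance cutoff. The compiled
#' sizes N_theta, N_C, N_H must all be at least 1.
#'
#' @param spec a [feature_spec()].
#' @param reference atom data.frame (`elety`, `resno`, `x`, `y`, `z`) of the
#'   reference frame; all frames to be featurized must share its atom order.
#' @return an object of class `compiled_feature_spec`.
#' @export
compile_feature_spec <- function(spec, reference) {
  stopifnot(inherits(spec, "feature_spec"),
            all(c("elety", "resno", "x", "y", "z") %in% names(reference)))
  idx <- atom_index(reference)

  quads <- list(); labels <- character(0)
  for (k in seq_len(nrow(spec$torsions))) {
    resno <- spec$torsions$resno[k]; angle <- spec$torsions$angle[k]
    pat <- torsion_atom_patterns(angle)
    at <- vapply(pat, function(p) lookup_atom(idx, resno + p$off, p$alt),
                 integer(1))
    if (anyNA(at)) next  # residue lacks this angle: drop at compilation
    quads[[length(quads) + 1L]] <- at
    labels <- c(labels, paste0(angle, "_", resno))
  }
  torsion_idx <- if (length(quads)) do.call(rbind, quads) else
    matrix(integer(0), ncol = 4L)

  ca_pairs <- enumerate_ca_pairs(spec)
  ca_i <- vapply(ca_pairs[, 1L], function(r) lookup_atom(idx, r, "CA"), integer(1))
  ca_j <- vapply(ca_pairs[, 2L], function(r) lookup_atom(idx, r, "CA"), integer(1))
  if (anyNA(ca_i) || anyNA(ca_j)) {
    miss <- unique(c(ca_pairs[is.na(ca_i), 1L], ca_pairs[is.na(ca_j), 2L]))
    stop("reference frame lacks CA atom(s) for residue(s): ",
         paste(miss, collapse = ", "))
  }

  cand <- spec$hbond_candidates %||% enumerate_hbond_candidates(spec, reference)
  admitted <- if (is.null(cand) || !nrow(cand)) NULL else
    select_hbond_pairs(reference, cand, spec$hbond_cutoff)

  n_theta <- nrow(torsion_idx); n_ca <- nrow(ca_pairs)
  n_hb <- if (is.null(admitted)) 0L else nrow(admitted)
  if (n_theta < 1L) stop("compiled spec has no torsions (N_theta must be >= 1)")
  if (n_ca < 1L) stop("compiled spec has no CA pairs (N_C must be >= 1)")
  if (n_hb < 1L)
    stop("no hydrogen-bond candidate within ", spec$hbond_cutoff,
         " Angstrom of the reference frame (N_H must be >= 1)")

  structure(list(spec = spec, torsion_idx = torsion_idx,
                 torsion_labels = labels, ca_pairs = ca_pairs,
                 ca_idx = cbind(ca_i, ca_j), hbond = admitted,
                 n_theta = n_theta, n_ca = n_ca, n_hbond = n_hb,
                 n_atoms = nrow(reference)),
            class = "compiled_feature_spec")
}

#' @export
print.compiled_feature_spec <- function(x, ...) {
  cat("Compiled feature spec: N_theta =", x$n_theta, ", N_C =", x$n_ca,
      ", N_H =", x$n_hbond, "\n")
  invisible(x)
}

#' Featurize one frame
#'
#' @param coords numeric matrix `n_atoms x 3` in the compiled reference atom
#'   order, or an atom data.frame with `x`, `y`, `z` columns.
#' @param cspec a [compile_feature_spec()] result.
#' @return list with numeric vectors `theta` (radians), `ca_dist`,
#'   `hbond_dist` (Angstrom).
#' @export
featurize_frame <- function(coords, cspec) {
  stopifnot(inherits(cspec, "compiled_feature_spec"))
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  if (nrow(coords) != cspec$n_atoms)
    stop("frame has ", nrow(coords), " atoms; compiled reference has ",
         cspec$n_atoms)
  th <- vapply(seq_len(cspec$n_theta), function(k) {
    q <- cspec$torsion_idx[k, ]
    compute_dihedral(coords[q[1L], ], coords[q[2L], ], coords[q[3L], ],
                     coords[q[4L], ])
  }, numeric(1))
  names(th) <- cspec$torsion_labels
  ca <- sqrt(rowSums((coords[cspec$ca_idx[, 1L], , drop = FALSE] -
                        coords[cspec$ca_idx[, 2L], , drop = FALSE])^2))
  names(ca) <- paste0("ca_", cspec$ca_pairs[, 1L], "_", cspec$ca_pairs[, 2L])
  hb <- sqrt(rowSums((coords[cspec$hbond$i, , drop = FALSE] -
                        coords[cspec$hbond$j, , drop = FALSE])^2))
  names(hb) <- paste0("hb_", cspec$hbond$donor_resno, cspec$hbond$donor_atom,
                      "_", cspec$hbond$acceptor_resno, cspec$hbond$acceptor_atom)
  list(theta = th, ca_dist = ca, hbond_dist = hb)
}

#' Featurize a list of frames
#'
#' @param frames list of coordinate matrices (`n_atoms x 3`, reference atom
#'   order), e.g. from [read_pdb_frames()].
#' @param cspec a [compile_feature_spec()] result.
#' @param ligand ligand label(s), recycled over frames.
#' @param replica replica label(s), recycled over frames.
#' @param keep_coords store the CA-selection coordinates for the RMSD stage
#'   (default `TRUE`).
#' @return a [frame_features()] object.
#' @export
featurize_frames <- function(frames, cspec, ligand = "L1", replica = 1L,
                             keep_coords = TRUE) {
  n <- length(frames)
  stopifnot(n >= 1L)
  feats <- lapply(frames, featurize_frame, cspec = cspec)
  ca_sel <- sort(unique(as.vector(cspec$ca_idx)))
  coords <- NULL
  if (keep_coords) {
    coords <- t(vapply(frames, function(f) {
      if (is.data.frame(f)) f <- as.matrix(f[, c("x", "y", "z")])
      as.vector(t(f[ca_sel, , drop = FALSE]))
    }, numeric(3L * length(ca_sel))))
  }
  frame_features(do.call(rbind, lapply(feats, `[[`, "theta")),
                 do.call(rbind, lapply(feats, `[[`, "ca_dist")),
                 do.call(rbind, lapply(feats, `[[`, "hbond_dist")),
                 ligand = rep_len(ligand, n), replica = rep_len(replica, n),
                 coords = coords)
}
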