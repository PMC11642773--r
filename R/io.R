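# Readers and writers: feature CSV, efficacy CSV (long format with medians
# on load), fraction CSV, truth/model JSON, feature-spec YAML, and
# multi-MODEL PDB adapters.

#' Write frame features as CSV
#'
#' Fixed header: `ligand, replica, frame, [template,] theta_*, ca_*, hb_*`.
#'
#' @param features a [frame_features()] object.
#' @param path output file.
#' @export
write_frames_csv <- function(features, path) {
  df <- data.frame(ligand = features$ligand, replica = features$replica,
                   frame = features$frame, stringsAsFactors = FALSE)
  if (!is.null(features$template)) df$template <- features$template
  df <- cbind(df, as.data.frame(features$theta),
              as.data.frame(features$ca_dist),
              as.data.frame(features$hbond_dist))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read frame features from CSV
#'
#' @param path file written by [write_frames_csv()].
#' @return a [frame_features()] object (coordinates are not stored in CSV).
#' @export
read_frames_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ligand", "replica", "frame")
  if (!all(need %in% names(df)))
    stop("feature CSV lacks required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  th <- grep("^theta_", names(df)); ca <- grep("^ca_", names(df))
  hb <- grep("^hb_", names(df))
  if (!length(th) || !length(ca) || !length(hb))
    stop("feature CSV must contain theta_*, ca_* and hb_* columns")
  frame_features(as.matrix(df[th]), as.matrix(df[ca]), as.matrix(df[hb]),
                 ligand = df$ligand, replica = df$replica, frame = df$frame,
                 template = df$template)
}

#' Write a fraction table as CSV
#'
#' @param fractions ligand x conformation matrix with rows summing to 1.
#' @param path output file.
#' @export
write_fractions_csv <- function(fractions, path) {
  df <- data.frame(ligand = rownames(fractions), as.data.frame(fractions),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a fraction table from CSV
#'
#' Validates that every row sums to one (within 1e-6) and that all entries
#' lie in [0, 1].
#'
#' @param path file written by [write_fractions_csv()].
#' @return ligand x conformation matrix.
#' @export
read_fractions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  f <- as.matrix(df[, -1L, drop = FALSE])
  rownames(f) <- df[[1L]]
  if (any(f < 0 | f > 1))
    stop("fraction entries must lie in [0, 1]")
  bad <- abs(rowSums(f) - 1) > 1e-6
  if (any(bad))
    stop("fraction row(s) not summing to 1: ",
         paste(rownames(f)[bad], collapse = ", "))
  f
}

#' Read an efficacy table
#'
#' Accepts either the wide format (`ligand, E_G, E_B`) or the long assay
#' format (`ligand, pathway, assay, value` with pathway in `{G, B}`), in
#' which case per-ligand medians over assays are computed on load.
#'
#' @param path CSV file.
#' @return data.frame with columns `ligand`, `E_G`, `E_B`.
#' @export
read_efficacy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("E_G", "E_B") %in% names(df)))
    return(df[, c("ligand", "E_G", "E_B")])
  if (!all(c("ligand", "pathway", "value") %in% names(df)))
    stop("efficacy CSV must have columns ligand,E_G,E_B or ligand,pathway,value")
  med <- stats::aggregate(value ~ ligand + pathway, df, stats::median)
  wide <- stats::reshape(med, idvar = "ligand", timevar = "pathway",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "E_", names(wide))
  if (!all(c("E_G", "E_B") %in% names(wide)))
    stop("efficacy CSV must contain both pathways G and B")
  rownames(wide) <- NULL
  wide[, c("ligand", "E_G", "E_B")]
}

#' Write synthetic ground truth as JSON
#'
#' @param truth a [synthetic_truth()] object.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$mixture_weights <- as.data.frame(x$mixture_weights)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read synthetic ground truth from JSON
#'
#' @param path file written by [write_truth_json()].
#' @return a [synthetic_truth()] object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mw <- x$mixture_weights
  rn <- mw[["_row"]]
  mw[["_row"]] <- NULL
  pw <- as.matrix(as.data.frame(mw))
  if (!is.null(rn)) rownames(pw) <- rn
  synthetic_truth(pw, x$intercept_G, x$slopes_G, x$intercept_B, x$slopes_B,
                  torsion_kappa = x$torsion_kappa,
                  coord_sigma = x$coord_sigma, hbond_sigma = x$hbond_sigma,
                  efficacy_noise_sd = x$efficacy_noise_sd, seed = x$seed)
}

#' Persist a conformation model as JSON
#'
#' Labels, medoid indices and the centroid RMSD/similarity matrices in one
#' JSON document (matrices as nested arrays).
#'
#' @param model a [conformation_model()].
#' @param path output file.
#' @export
write_conformation_json <- function(model, path) {
  x <- list(H = model$hp$H, delta = model$hp$delta, C = model$hp$C,
            weights = as.list(unclass(model$hp$weights)),
            subsample = model$subsample, hier_labels = model$hier_labels,
            medoid_index = model$medoid_index,
            conf_of_cluster = model$conf_of_cluster,
            conf_labels = model$conf_labels,
            D_rmsd = model$D_rmsd, S_rmsd = model$S_rmsd,
            normalizers = as.list(model$normalizers),
            fractions = as.data.frame(model$fractions),
            ligands = model$ligands)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Persist distance matrices as CSV with a JSON sidecar
#'
#' The combined matrix goes to `<path>.csv`; weights and the three
#' component normalizers go to `<path>.json`.
#'
#' @param dm a `distance_matrices` object from [combine_distances()].
#' @param path output stem (without extension).
#' @export
write_distances <- function(dm, path) {
  utils::write.table(dm$D, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(weights = as.list(unclass(dm$weights)),
                            normalizers = as.list(dm$normalizers)),
                       paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a feature specification as YAML
#' @param spec a [feature_spec()].
#' @param path output file.
#' @export
write_feature_spec <- function(spec, path) {
  x <- unclass(spec)
  x$torsions <- lapply(seq_len(nrow(x$torsions)), function(i)
    list(resno = x$torsions$resno[i], angle = x$torsions$angle[i]))
  if (!is.null(x$hbond_candidates))
    x$hbond_candidates <- lapply(seq_len(nrow(spec$hbond_candidates)),
                                 function(i) as.list(spec$hbond_candidates[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a feature specification from YAML
#'
#' Understands both the explicit form written by [write_feature_spec()] and
#' a compact form with `torsion_ranges` (residue ranges crossed with
#' `torsion_angles`), as used by the bundled receptor spec.
#'
#' @param path YAML file.
#' @return a [feature_spec()].
#' @export
read_feature_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$torsion_ranges)) {
    res <- unlist(lapply(x$torsion_ranges, function(r) seq(r$from, r$to)))
    torsions <- expand.grid(resno = res, angle = x$torsion_angles,
                            stringsAsFactors = FALSE)
  } else {
    torsions <- do.call(rbind, lapply(x$torsions, as.data.frame))
  }
  cand <- NULL
  if (!is.null(x$hbond_candidates))
    cand <- do.call(rbind, lapply(x$hbond_candidates, as.data.frame))
  hb <- x$hbond %||% list()
  args <- list(torsions = torsions,
               ca_residues = unlist(x$ca_residues),
               hbond_candidates = cand,
               hbond_cutoff = hb$cutoff %||% x$hbond_cutoff %||% 8.0,
               min_sequence_separation = x$min_sequence_separation %||% 2L)
  da <- unlist(hb$donor_atoms %||% x$donor_atoms)
  if (!is.null(da)) args$donor_atoms <- da
  aa <- unlist(hb$acceptor_atoms %||% x$acceptor_atoms)
  if (!is.null(aa)) args$acceptor_atoms <- aa
  do.call(feature_spec, args)
}

#' Write frames as a multi-MODEL PDB pseudo-structure
#'
#' One MODEL per frame; one CA pseudo-atom per stored atom. Intended for
#' the synthetic module's coordinate output so the RMSD stage can run from
#' standard structure files.
#'
#' @param features a [frame_features()] object with coordinates.
#' @param path output file.
#' @param max_frames cap on frames written (PDB is verbose).
#' @export
write_frames_pdb <- function(features, path, max_frames = Inf) {
  if (is.null(features$coords)) stop("features carry no coordinates")
  n <- min(n_frames(features), max_frames)
  m <- ncol(features$coords) / 3L
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(features$coords[f, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(m), seq_len(m), xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read frames from a multi-MODEL PDB file
#'
#' Adapter over [bio3d::read.pdb()]: yields one atom coordinate matrix per
#' MODEL record, in file atom order, plus the atom table of the first
#' model.
#'
#' @param path PDB file.
#' @return list with `frames` (list of `n_atoms x 3` matrices) and `atoms`
#'   (data.frame with `elety`, `resno`, `x`, `y`, `z` of the first frame).
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  atoms <- pdb$atom[, c("elety", "resno", "x", "y", "z")]
  list(frames = frames, atoms = atoms)
}
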