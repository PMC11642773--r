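#' Per-frame feature container
#'
#' Holds the three feature blocks describing each configuration of a
#' receptor-ligand ensemble: `theta` (torsion angles, radians), `ca_dist`
#' (pairwise alpha-carbon distances, Angstrom) and `hbond_dist`
#' (hydrogen-bond donor-acceptor distances, Angstrom), together with
#' ligand/replica/frame identity and, optionally, the coordinates of the
#' RMSD atom selection (one row per frame, xyz-interleaved).
#'
#' @param theta numeric matrix, frames x n_torsions, angles in radians.
#' @param ca_dist numeric matrix, frames x n_ca_pairs, nonnegative.
#' @param hbond_dist numeric matrix, frames x n_hbond_pairs, nonnegative.
#' @param ligand character/factor of length n_frames.
#' @param replica replica identifier per frame (default 1).
#' @param frame frame index per frame (default running index within
#'   ligand/replica).
#' @param coords optional numeric matrix, frames x (3 * n_atoms), coordinates
#'   of the RMSD atom selection as x1,y1,z1,x2,...
#' @param template optional integer vector of planted conformation labels
#'   (synthetic data only).
#' @return an object of class `frame_features`.
#' @export
frame_features <- function(theta, ca_dist, hbond_dist, ligand,
                           replica = 1L, frame = NULL, coords = NULL,
                           template = NULL) {
  theta <- as.matrix(theta); ca_dist <- as.matrix(ca_dist)
  hbond_dist <- as.matrix(hbond_dist)
  n <- nrow(theta)
  if (nrow(ca_dist) != n || nrow(hbond_dist) != n)
    stop("feature blocks disagree on the number of frames")
  if (length(ligand) != n)
    stop("`ligand` must have one entry per frame")
  if (any(theta < -pi | theta >= pi))
    theta <- wrap_angle(theta)
  if (any(ca_dist < 0) || any(hbond_dist < 0))
    stop("distance features must be nonnegative")
  replica <- rep_len(replica, n)
  if (is.null(frame)) {
    frame <- stats::ave(seq_len(n), paste(ligand, replica),
                        FUN = seq_along)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n) stop("`coords` must have one row per frame")
    if (ncol(coords) %% 3L != 0L) stop("`coords` must have 3 columns per atom")
  }
  if (!is.null(template) && length(template) != n)
    stop("`template` must have one entry per frame")
  if (is.null(colnames(theta)))
    colnames(theta) <- paste0("theta_", seq_len(ncol(theta)))
  if (is.null(colnames(ca_dist)))
    colnames(ca_dist) <- paste0("ca_", seq_len(ncol(ca_dist)))
  if (is.null(colnames(hbond_dist)))
    colnames(hbond_dist) <- paste0("hb_", seq_len(ncol(hbond_dist)))
  structure(list(theta = theta, ca_dist = ca_dist, hbond_dist = hbond_dist,
                 ligand = as.character(ligand), replica = replica,
                 frame = as.integer(frame), coords = coords,
                 template = template),
            class = "frame_features")
}

#' @export
print.frame_features <- function(x, ...) {
  cat("Frame features:", n_frames(x), "frames,",
      length(unique(x$ligand)), "ligand(s)\n")
  cat("  blocks: theta[", ncol(x$theta), "], ca[", ncol(x$ca_dist),
      "], hbond[", ncol(x$hbond_dist), "]",
      if (!is.null(x$coords)) paste0(", coords[", ncol(x$coords) / 3L, " atoms]"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a feature set
#' @param x a `frame_features` object.
#' @return integer frame count.
#' @export
n_frames <- function(x) nrow(x$theta)

#' Subset frames
#' @param x a `frame_features` object.
#' @param i frame indices (any standard row index).
#' @param ... unused.
#' @return a `frame_features` object with the selected frames.
#' @export
`[.frame_features` <- function(x, i, ...) {
  frame_features(x$theta[i, , drop = FALSE],
                 x$ca_dist[i, , drop = FALSE],
                 x$hbond_dist[i, , drop = FALSE],
                 ligand = x$ligand[i],
                 replica = x$replica[i],
                 frame = x$frame[i],
                 coords = if (!is.null(x$coords)) x$coords[i, , drop = FALSE],
                 template = if (!is.null(x$template)) x$template[i])
}

#' Concatenate frame feature sets
#' @param ... `frame_features` objects with matching block widths.
#' @param deparse.level unused.
#' @return a single `frame_features` object.
#' @export
rbind.frame_features <- function(..., deparse.level = 1) {
  xs <- list(...)
  coords <- lapply(xs, `[[`, "coords")
  has_coords <- !vapply(coords, is.null, logical(1))
  tmpl <- lapply(xs, `[[`, "template")
  has_tmpl <- !vapply(tmpl, is.null, logical(1))
  frame_features(do.call(rbind, lapply(xs, `[[`, "theta")),
                 do.call(rbind, lapply(xs, `[[`, "ca_dist")),
                 do.call(rbind, lapply(xs, `[[`, "hbond_dist")),
                 ligand = unlist(lapply(xs, `[[`, "ligand")),
                 replica = unlist(lapply(xs, `[[`, "replica")),
                 frame = unlist(lapply(xs, `[[`, "frame")),
                 coords = if (all(has_coords)) do.call(rbind, coords),
                 template = if (all(has_tmpl)) unlist(tmpl))
}
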