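# Synthetic ensemble generator: planted conformation templates, ligand-
# specific mixtures over them, and efficacies from the linear forward model.
# This module defines the desk-scale study conditions under which every
# downstream stage is tested without molecular-dynamics trajectories.

#' Generate well-separated conformation templates
#'
#' Each template is a planted conformation: mean torsions (uniform on the
#' circle), mean pseudo-residue coordinates (uniform in a box whose side
#' scales with the requested separation) and mean H-bond distances. A
#' candidate template is accepted only if, against every accepted template,
#' each feature block's RMS distance is at least `separation` times that
#' block's reference noise scale; placement fails after 1000 rejected
#' attempts.
#'
#' @param n_templates number of templates (>= 2).
#' @param n_torsions torsions per template.
#' @param n_residues pseudo-residues per template (>= 4).
#' @param separation minimum inter-template distance in units of the
#'   per-block reference noise scale.
#' @param seed integer RNG seed; templates are deterministic given it.
#' @param n_hbond H-bond distances per template.
#' @param noise_ref per-block reference noise scales used by the separation
#'   rule: torsion scale in degrees, coordinate and H-bond scales in
#'   Angstrom.
#' @return list of `conformation_template` objects (fields `template_id`,
#'   `mean_torsions`, `mean_coords`, `mean_hbond_distances`).
#' @export
make_templates <- function(n_templates, n_torsions = 10L, n_residues = 8L,
                           separation = 6, seed = 1L, n_hbond = 6L,
                           noise_ref = c(theta_deg = 10, coord = 0.5,
                                         hbond = 0.5)) {
  if (n_templates < 2L) stop("n_templates must be at least 2")
  if (n_residues < 4L) stop("n_residues must be at least 4")
  if (separation <= 0) stop("separation must be positive")
  set.seed(as.integer(seed))
  box <- max(10, 3 * separation * noise_ref[["coord"]])
  hmax <- 2 + max(10, 3 * separation * noise_ref[["hbond"]])
  pair_rule <- feature_spec(
    torsions = data.frame(resno = 1L, angle = "phi"),  # unused; CA rule only
    ca_residues = seq_len(n_residues))
  pairs <- enumerate_ca_pairs(pair_rule)

  ca_of <- function(coords) {
    sqrt(rowSums((coords[pairs[, 1L], , drop = FALSE] -
                    coords[pairs[, 2L], , drop = FALSE])^2))
  }
  templates <- list()
  attempts <- 0L
  while (length(templates) < n_templates) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("could not place ", n_templates, " templates at separation ",
           separation, " within 1000 attempts")
    cand <- list(
      template_id = length(templates) + 1L,
      mean_torsions = stats::runif(n_torsions, -pi, pi),
      mean_coords = matrix(stats::runif(3L * n_residues, 0, box),
                           ncol = 3L),
      mean_hbond_distances = stats::runif(n_hbond, 2, hmax))
    ok <- all(vapply(templates, function(t) {
      torsion_distance(cand$mean_torsions, t$mean_torsions) >=
        separation * noise_ref[["theta_deg"]] &&
      rms_feature_distance(ca_of(cand$mean_coords), ca_of(t$mean_coords)) >=
        separation * noise_ref[["coord"]] &&
      rms_feature_distance(cand$mean_hbond_distances,
                           t$mean_hbond_distances) >=
        separation * noise_ref[["hbond"]]
    }, logical(1)))
    if (ok) templates[[length(templates) + 1L]] <-
        structure(cand, class = "conformation_template")
  }
  templates
}

#' Ground truth of a synthetic study
#'
#' Houses the ligand-specific mixture weights over the planted templates,
#' the forward-model regression coefficients for both pathways, and the
#' noise parameters, so that fraction recovery can be scored against the
#' mixture weights themselves rather than empirical label frequencies.
#'
#' @param mixture_weights ligand x template matrix of probabilities; rows
#'   must sum to 1 (within 1e-9) and be nonnegative.
#' @param intercept_G,slopes_G,intercept_B,slopes_B forward-model intercepts
#'   and per-template slopes (efficacy percent per unit fraction) for the
#'   two pathways; slope length must equal the number of templates.
#' @param torsion_kappa von Mises concentration of the angular noise
#'   (`Inf` = no noise).
#' @param coord_sigma isotropic positional jitter, Angstrom (>= 0).
#' @param hbond_sigma H-bond distance jitter, Angstrom (>= 0); draws are
#'   truncated at zero.
#' @param efficacy_noise_sd additive efficacy noise, percent.
#' @param seed integer root seed for sampling and efficacy noise.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(mixture_weights, intercept_G, slopes_G,
                            intercept_B, slopes_B, torsion_kappa = 50,
                            coord_sigma = 0.3, hbond_sigma = 0.3,
                            efficacy_noise_sd = 2, seed = 1L) {
  mixture_weights <- as.matrix(mixture_weights)
  if (any(mixture_weights < 0))
    stop("mixture weights must be nonnegative")
  if (any(abs(rowSums(mixture_weights) - 1) > 1e-9))
    stop("each mixture-weight row must sum to 1")
  k <- ncol(mixture_weights)
  if (length(slopes_G) != k || length(slopes_B) != k)
    stop("slope length must match the number of templates")
  if (coord_sigma < 0 || hbond_sigma < 0 || efficacy_noise_sd < 0)
    stop("noise parameters must be nonnegative")
  if (is.null(rownames(mixture_weights)))
    rownames(mixture_weights) <- paste0("L", seq_len(nrow(mixture_weights)))
  structure(list(mixture_weights = mixture_weights,
                 intercept_G = intercept_G, slopes_G = slopes_G,
                 intercept_B = intercept_B, slopes_B = slopes_B,
                 torsion_kappa = torsion_kappa, coord_sigma = coord_sigma,
                 hbond_sigma = hbond_sigma,
                 efficacy_noise_sd = efficacy_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

template_features <- function(template, n_residues_sep = 2L) {
  spec <- feature_spec(torsions = data.frame(resno = 1L, angle = "phi"),
                       ca_residues = seq_len(nrow(template$mean_coords)),
                       min_sequence_separation = n_residues_sep)
  pairs <- enumerate_ca_pairs(spec)
  mc <- template$mean_coords
  # same scalar arithmetic as sample_frames() so the zero-noise limit
  # reproduces template features bit-identically
  dx <- mc[pairs[, 1L], 1L] - mc[pairs[, 2L], 1L]
  dy <- mc[pairs[, 1L], 2L] - mc[pairs[, 2L], 2L]
  dz <- mc[pairs[, 1L], 3L] - mc[pairs[, 2L], 3L]
  ca <- sqrt(dx^2 + dy^2 + dz^2)
  list(theta = template$mean_torsions, ca = ca,
       hb = template$mean_hbond_distances, pairs = pairs)
}

#' Sample synthetic frames from planted templates
#'
#' Per ligand, frame template labels are multinomial draws from that
#' ligand's mixture-weight row. Torsions are von Mises noise around the
#' template means; pseudo-residue coordinates get isotropic Gaussian jitter
#' (CA pair distances are recomputed from the jittered coordinates with the
#' "at least one residue in between" rule); H-bond distances get Gaussian
#' jitter truncated at zero. Deterministic given `truth$seed`.
#'
#' @param truth a [synthetic_truth()] object.
#' @param templates list from [make_templates()]; columns of the mixture
#'   weights index it.
#' @param n_frames_per_ligand frames per ligand (split over replicas).
#' @param n_replicas replica count per ligand; must divide
#'   `n_frames_per_ligand`.
#' @return a [frame_features()] object carrying coordinates and the true
#'   template label of every frame in `$template`.
#' @export
sample_frames <- function(truth, templates, n_frames_per_ligand,
                          n_replicas = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pw <- truth$mixture_weights
  if (ncol(pw) != length(templates))
    stop("mixture-weight columns must index the templates")
  if (n_frames_per_ligand %% n_replicas != 0L)
    stop("n_replicas must divide n_frames_per_ligand")
  set.seed(truth$seed)
  tf <- lapply(templates, template_features)
  n_tor <- length(tf[[1L]]$theta)
  n_res <- nrow(templates[[1L]]$mean_coords)
  L <- nrow(pw)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    n <- n_frames_per_ligand
    lab <- sample.int(ncol(pw), n, replace = TRUE, prob = pw[l, ])
    theta <- matrix(0, n, n_tor)
    for (c in unique(lab)) {
      rows <- which(lab == c)
      mu <- rep(tf[[c]]$theta, each = length(rows))
      theta[rows, ] <- rvonmises(length(rows) * n_tor, mu,
                                 truth$torsion_kappa)
    }
    mean_xyz <- t(vapply(templates, function(t) as.vector(t$mean_coords),
                         numeric(3L * n_res)))
    coords <- mean_xyz[lab, , drop = FALSE]
    if (truth$coord_sigma > 0)
      coords <- coords + stats::rnorm(length(coords), 0, truth$coord_sigma)
    # coords stored column-major over mean_coords: (x1..xM, y1..yM, z1..zM)
    pairs <- tf[[1L]]$pairs
    ca <- matrix(0, n, nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      dx <- coords[, i] - coords[, j]
      dy <- coords[, n_res + i] - coords[, n_res + j]
      dz <- coords[, 2L * n_res + i] - coords[, 2L * n_res + j]
      ca[, p] <- sqrt(dx^2 + dy^2 + dz^2)
    }
    mean_hb <- t(vapply(templates, function(t) t$mean_hbond_distances,
                        numeric(length(tf[[1L]]$hb))))
    hb <- mean_hb[lab, , drop = FALSE]
    if (truth$hbond_sigma > 0) {
      jit <- matrix(stats::rnorm(length(hb), 0, truth$hbond_sigma), nrow(hb))
      hb2 <- hb + jit
      while (any(hb2 <= 0)) {  # truncate at > 0 by redrawing
        bad <- hb2 <= 0
        hb2[bad] <- hb[bad] + stats::rnorm(sum(bad), 0, truth$hbond_sigma)
      }
      hb <- hb2
    }
    # xyz-interleave coordinates for the RMSD stage (x1,y1,z1,x2,...)
    inter <- as.vector(rbind(seq_len(n_res), n_res + seq_len(n_res),
                             2L * n_res + seq_len(n_res)))
    out[[l]] <- frame_features(
      theta, ca, hb,
      ligand = rep(rownames(pw)[l], n),
      replica = rep(seq_len(n_replicas), each = n / n_replicas),
      coords = coords[, inter, drop = FALSE],
      template = lab)
  }
  do.call(rbind, out)
}

#' Forward-model efficacies from mixture weights
#'
#' \eqn{E_{l} = \beta_0 + \sum_c \beta_c \pi_{l,c}} plus Gaussian noise,
#' per pathway. Deterministic given `truth$seed`.
#'
#' @param truth a [synthetic_truth()] object.
#' @return data.frame with columns `ligand`, `E_G`, `E_B` (percent of the
#'   reference agonist).
#' @export
make_efficacies <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pw <- truth$mixture_weights
  set.seed(truth$seed + 1000003L)
  eg <- truth$intercept_G + drop(pw %*% truth$slopes_G)
  eb <- truth$intercept_B + drop(pw %*% truth$slopes_B)
  if (truth$efficacy_noise_sd > 0) {
    eg <- eg + stats::rnorm(nrow(pw), 0, truth$efficacy_noise_sd)
    eb <- eb + stats::rnorm(nrow(pw), 0, truth$efficacy_noise_sd)
  }
  data.frame(ligand = rownames(pw), E_G = eg, E_B = eb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a complete synthetic study
#'
#' The default arguments are the package's desk-scale study conditions:
#' 6 planted conformations, 18 pseudo-ligands with Dirichlet mixture rows,
#' 1500 frames per ligand in 3 replicas, well-separated templates, and
#' efficacies from the linear forward model with 2% noise. Slopes span the
#' percent-efficacy range with a fixed pattern so that the two pathways
#' disagree on some conformations (selectivity).
#'
#' @param n_templates,n_ligands,n_frames_per_ligand,n_replicas study sizes.
#' @param separation template separation passed to [make_templates()].
#' @param mixture_alpha Dirichlet concentration of the mixture rows.
#' @param torsion_kappa,coord_sigma,hbond_sigma,efficacy_noise_sd noise
#'   levels (see [synthetic_truth()]).
#' @param seed integer root seed; all randomness derives from it.
#' @return list with `features` ([frame_features()]), `efficacies`
#'   (data.frame), `truth` ([synthetic_truth()]), `templates`.
#' @export
synthetic_study <- function(n_templates = 6L, n_ligands = 18L,
                            n_frames_per_ligand = 1500L, n_replicas = 3L,
                            separation = 6, mixture_alpha = 0.6,
                            torsion_kappa = 50, coord_sigma = 0.3,
                            hbond_sigma = 0.3, efficacy_noise_sd = 2,
                            seed = 1L) {
  seed <- as.integer(seed)
  templates <- make_templates(n_templates, separation = separation,
                              seed = seed)
  set.seed(seed + 500009L)
  pw <- rdirichlet(n_ligands, rep(mixture_alpha, n_templates))
  rownames(pw) <- sprintf("L%02d", seq_len(n_ligands))
  slopes_G <- seq(100, -40, length.out = n_templates)
  slopes_B <- 0.9 * slopes_G[c(seq_len(n_templates)[-1L], 1L)]
  truth <- synthetic_truth(pw, intercept_G = 0, slopes_G = slopes_G,
                           intercept_B = 0, slopes_B = slopes_B,
                           torsion_kappa = torsion_kappa,
                           coord_sigma = coord_sigma,
                           hbond_sigma = hbond_sigma,
                           efficacy_noise_sd = efficacy_noise_sd,
                           seed = seed + 700001L)
  features <- sample_frames(truth, templates, n_frames_per_ligand,
                            n_replicas)
  list(features = features, efficacies = make_efficacies(truth),
       truth = truth, templates = templates)
}
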