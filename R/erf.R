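# Efficacy response functions: per-conformation feature densities weighted
# by mean regression slopes, general/selective activation functions, and
# their integral scores.

# Histogram density over bins anchored at the data range (so bins need not
# align with the domain edges), renormalized to integrate to one over the
# evaluation domain. Returned as a step function evaluator.
histogram_density <- function(samples, n_bins, domain) {
  rng <- range(samples)
  if (rng[1L] == rng[2L]) {
    binw <- diff(domain) / n_bins
    rng <- rng + c(-binw / 2, binw / 2)
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- graphics::hist(samples, breaks = breaks, plot = FALSE)$counts
  binw <- diff(breaks[1:2])
  dens <- counts / (length(samples) * binw)
  # exact integral over the evaluation domain: sum of bin-overlap lengths
  lo <- pmax(breaks[-length(breaks)], domain[1L])
  hi <- pmin(breaks[-1L], domain[2L])
  norm <- sum(pmax(hi - lo, 0) * dens)
  if (norm <= 0)
    stop("density has no mass inside the evaluation domain")
  eval_at <- function(x) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE)
    out <- numeric(length(x))
    ok <- i >= 1L & i <= length(dens)
    out[ok] <- dens[i[ok]] / norm
    out
  }
  list(eval = eval_at, breaks = breaks, density = dens / norm, norm = norm)
}

#' Periodic (torsion) feature density
#'
#' Histogram-based density of a circular sample: every sample is
#' triplicated at +/- one period before binning so that mass near the
#' +/- pi seam spreads continuously across it, then the density is
#' renormalized so its integral over \eqn{[-\pi, \pi]} is one.
#'
#' @param samples angles in radians.
#' @param n_bins bins per period (default 72, i.e. 5-degree bins).
#' @return list with `eval` (vectorized density function on
#'   \eqn{[-\pi, \pi]}), `breaks`, `density`, `norm`.
#' @export
periodic_density <- function(samples, n_bins = 72L) {
  if (!length(samples)) stop("empty sample set")
  samples <- wrap_angle(samples)
  trip <- c(samples - 2 * pi, samples, samples + 2 * pi)
  histogram_density(trip, 3L * n_bins, c(-pi, pi))
}

#' Linear (distance) feature density
#'
#' Histogram density over a fixed domain, normalized to integrate to one.
#'
#' @param samples numeric samples; all must lie inside `domain`.
#' @param n_bins number of bins (default 100).
#' @param domain length-2 interval covering the samples.
#' @return list with `eval`, `breaks`, `density`, `norm` as in
#'   [periodic_density()].
#' @export
linear_density <- function(samples, n_bins = 100L, domain = range(samples)) {
  if (!length(samples)) stop("empty sample set")
  if (diff(domain) <= 0) stop("domain must have positive width")
  if (any(samples < domain[1L] | samples > domain[2L]))
    stop("samples outside the stated domain")
  breaks <- seq(domain[1L], domain[2L], length.out = n_bins + 1L)
  counts <- graphics::hist(samples, breaks = breaks, plot = FALSE)$counts
  binw <- diff(breaks[1:2])
  dens <- counts / (length(samples) * binw)
  norm <- sum(dens * binw)
  eval_at <- function(x) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE)
    out <- numeric(length(x))
    ok <- i >= 1L & i <= length(dens)
    out[ok] <- dens[i[ok]] / norm
    out
  }
  list(eval = eval_at, breaks = breaks, density = dens / norm, norm = norm)
}

#' Efficacy response function on a grid
#'
#' \eqn{r(x) = \sum_c \beta_c \, p_c(x)}: each conformation's feature
#' density weighted by that conformation's mean regression slope and
#' summed. Conformations without samples are excluded with a warning that
#' reports the excluded slope mass.
#'
#' @param samples_by_conformation list of numeric sample vectors, one per
#'   conformation (in slope order).
#' @param mean_slopes numeric slope per conformation.
#' @param grid evaluation points.
#' @param periodic torsion feature (`TRUE`) or linear feature (`FALSE`).
#' @param n_bins histogram bins (per period if periodic).
#' @param domain evaluation domain (defaults to \eqn{[-\pi, \pi]} if
#'   periodic, else the grid range).
#' @return numeric response values on `grid`.
#' @export
erf_response <- function(samples_by_conformation, mean_slopes, grid,
                         periodic = TRUE,
                         n_bins = if (periodic) 72L else 100L,
                         domain = if (periodic) c(-pi, pi) else range(grid)) {
  if (length(samples_by_conformation) != length(mean_slopes))
    stop("one slope per conformation is required")
  have <- lengths(samples_by_conformation) > 0L
  if (!all(have)) {
    warning("excluding ", sum(!have), " conformation(s) without samples ",
            "(slope mass ", signif(sum(abs(mean_slopes[!have])), 4), ")")
  }
  r <- numeric(length(grid))
  for (c in which(have)) {
    d <- if (periodic) periodic_density(samples_by_conformation[[c]], n_bins)
         else linear_density(samples_by_conformation[[c]], n_bins, domain)
    r <- r + mean_slopes[c] * d$eval(grid)
  }
  r
}

#' General activation function
#'
#' Nonzero where both pathways' response functions are strictly same-signed:
#' \eqn{a(x) = \min(|r_G|, |r_B|)} there, 0 elsewhere (zeros excluded).
#'
#' @param r_G,r_B response values on a shared grid.
#' @return nonnegative values on the grid.
#' @export
general_activation <- function(r_G, r_B) {
  if (length(r_G) != length(r_B)) stop("responses must share the grid")
  same <- (r_G > 0 & r_B > 0) | (r_G < 0 & r_B < 0)
  ifelse(same, pmin(abs(r_G), abs(r_B)), 0)
}

#' Selective activation function
#'
#' Nonzero where the two pathways' response functions are strictly
#' opposite-signed: \eqn{s(x) = |r_G - r_B|} there, 0 elsewhere.
#'
#' @param r_G,r_B response values on a shared grid.
#' @return nonnegative values on the grid.
#' @export
selective_activation <- function(r_G, r_B) {
  if (length(r_G) != length(r_B)) stop("responses must share the grid")
  opp <- (r_G > 0 & r_B < 0) | (r_G < 0 & r_B > 0)
  ifelse(opp, abs(r_G - r_B), 0)
}

#' Riemann activation score
#'
#' The sum of the function values on a uniform grid multiplied by the grid
#' spacing.
#'
#' @param values function values on the grid.
#' @param grid strictly increasing, uniformly spaced evaluation points.
#' @return scalar score.
#' @export
activation_score <- function(values, grid) {
  if (length(values) != length(grid)) stop("values and grid differ in length")
  sp <- diff(grid)
  if (any(sp <= 0) || max(abs(sp - sp[1L])) > 1e-8 * abs(sp[1L]))
    stop("grid must be strictly increasing and uniformly spaced")
  sp[1L] * sum(values)
}

erf_grid <- function(domain, n = 1000L) {
  seq(domain[1L], domain[2L], length.out = n)
}

feature_column <- function(features, feature) {
  blocks <- list(theta = features$theta, ca = features$ca_dist,
                 hb = features$hbond_dist)
  for (b in names(blocks)) {
    hit <- match(feature, colnames(blocks[[b]]))
    if (!is.na(hit))
      return(list(values = blocks[[b]][, hit], periodic = b == "theta"))
  }
  stop("unknown feature: ", feature)
}

#' Efficacy response profile of one structural feature
#'
#' Builds both pathways' response functions for a feature on a 1000-point
#' grid, the general and selective activation functions, and their integral
#' scores. Torsion features use the periodic density on \eqn{[-\pi, \pi]};
#' distance features use a linear density over the pooled sample range
#' padded by 5% per side.
#'
#' @param object a [conf_efficacy()] fit with cross-validation results
#'   (mean fold slopes are the response weights).
#' @param feature feature column name (e.g. `"theta_3"`, `"ca_7"`,
#'   `"hb_2"`).
#' @param n_bins histogram bin count override (`NULL` = block default).
#' @param n_grid evaluation points (default 1000).
#' @return object of class `erf_profile` with fields `grid`, `r_G`, `r_B`,
#'   `a`, `s`, `score_general`, `score_selective`.
#' @export
erf_profile <- function(object, feature, n_bins = NULL, n_grid = 1000L) {
  stopifnot(inherits(object, "conf_efficacy"))
  if (is.null(object$mean_slopes))
    stop("fit has no cross-validation fold slopes; refit with cv = TRUE")
  col <- feature_column(object$features, feature)
  labels <- object$model$conf_labels
  C <- object$hp$C
  samples <- split(col$values, factor(labels, levels = seq_len(C)))
  domain <- if (col$periodic) c(-pi, pi) else {
    r <- range(col$values); r + c(-1, 1) * 0.05 * diff(r)
  }
  grid <- erf_grid(domain, n_grid)
  nb <- n_bins %||% (if (col$periodic) 72L else 100L)
  r_G <- erf_response(samples, object$mean_slopes["G", ], grid,
                      periodic = col$periodic, n_bins = nb, domain = domain)
  r_B <- erf_response(samples, object$mean_slopes["B", ], grid,
                      periodic = col$periodic, n_bins = nb, domain = domain)
  a <- general_activation(r_G, r_B)
  s <- selective_activation(r_G, r_B)
  structure(list(feature = feature, periodic = col$periodic, grid = grid,
                 r_G = r_G, r_B = r_B, a = a, s = s,
                 score_general = activation_score(a, grid),
                 score_selective = activation_score(s, grid)),
            class = "erf_profile")
}

#' @export
print.erf_profile <- function(x, ...) {
  cat(sprintf("ERF profile of %s (%s): general score %.4g, selective score %.4g\n",
              x$feature, if (x$periodic) "periodic" else "linear",
              x$score_general, x$score_selective))
  invisible(x)
}

#' @export
plot.erf_profile <- function(x, ...) {
  lim <- range(x$r_G, x$r_B, 0)
  graphics::plot(x$grid, x$r_G, type = "l", col = "forestgreen",
                 ylim = lim, xlab = x$feature, ylab = "response", ...)
  graphics::lines(x$grid, x$r_B, col = "purple")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = c("G", "B"), lty = 1,
                   col = c("forestgreen", "purple"), bty = "n")
  invisible(x)
}

#' Activation scores of every feature
#'
#' Computes general and selective activation scores for all feature columns
#' and returns them ranked by the general score.
#'
#' @param object a [conf_efficacy()] fit with cross-validation results.
#' @param features character vector of feature names (default: all columns
#'   of all three blocks).
#' @param top_fraction optionally keep only this top fraction by general
#'   score (e.g. `0.02` for the top 2%); `NULL` keeps all.
#' @return data.frame with columns `feature`, `periodic`, `score_general`,
#'   `score_selective`, sorted by decreasing general score.
#' @export
erf_scores <- function(object, features = NULL, top_fraction = NULL) {
  stopifnot(inherits(object, "conf_efficacy"))
  features <- features %||% c(colnames(object$features$theta),
                              colnames(object$features$ca_dist),
                              colnames(object$features$hbond_dist))
  rows <- lapply(features, function(f) {
    p <- erf_profile(object, f)
    data.frame(feature = f, periodic = p$periodic,
               score_general = p$score_general,
               score_selective = p$score_selective,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score_general), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_fraction))
    out <- out[seq_len(max(1L, ceiling(top_fraction * nrow(out)))), ,
               drop = FALSE]
  out
}
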