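# The main fitting function: conformation-fraction efficacy model with
# grid-searched clustering hyperparameters and leave-one-out validation.

#' Fit a conformation-fraction efficacy model
#'
#' End-to-end fit: hyperparameters are selected by grid search under the
#' inner leave-one-out loss summed over both pathways, frames are clustered
#' into conformations at the selected point, per-ligand occupancy fractions
#' are computed over all frames, and each pathway's efficacy is regressed
#' on the fractions by minimum-norm least squares. With `cv = TRUE`
#' (default) the outer leave-one-out protocol is run as well: per fold, the
#' grid search and regression are repeated without the held-out ligand and
#' its efficacy is predicted; per-fold slopes feed the efficacy response
#' functions.
#'
#' @param features a [frame_features()] object with coordinates.
#' @param efficacies data.frame with columns `ligand`, `E_G`, `E_B`
#'   (percent of the reference agonist). Every ligand must have frames and
#'   both pathway values; this is validated before any computation.
#' @param grid an [efficacy_grid()].
#' @param stride clustering subsample stride (the pairwise distance matrix
#'   is quadratic in the number of clustered frames).
#' @param cv run the outer leave-one-out validation (default `TRUE`).
#' @return object of class `conf_efficacy`.
#' @export
conf_efficacy <- function(features, efficacies, grid, stride = 1L,
                          cv = TRUE) {
  stopifnot(inherits(features, "frame_features"),
            is.data.frame(efficacies),
            all(c("ligand", "E_G", "E_B") %in% names(efficacies)))
  if (anyNA(efficacies$E_G) || anyNA(efficacies$E_B))
    stop("missing efficacy for ligand(s): ",
         paste(efficacies$ligand[is.na(efficacies$E_G) |
                                   is.na(efficacies$E_B)], collapse = ", "))
  missing_frames <- setdiff(efficacies$ligand, unique(features$ligand))
  if (length(missing_frames))
    stop("no frames for ligand(s): ", paste(missing_frames, collapse = ", "))
  extra <- setdiff(unique(features$ligand), efficacies$ligand)
  if (length(extra))
    stop("missing efficacy for ligand(s): ", paste(extra, collapse = ", "))

  cache <- cluster_cache(features, stride)
  cv_res <- if (cv) outer_loo_cv(features, efficacies, grid, stride, cache)
  gs <- grid_search(features, efficacies, efficacies$ligand, grid, stride,
                    cache)
  model <- gs$model
  f <- model$fractions[efficacies$ligand, , drop = FALSE]
  fit_g <- fit_mlr(f, efficacies$E_G)
  fit_b <- fit_mlr(f, efficacies$E_B)

  mean_slopes <- NULL
  if (cv) {
    same <- vapply(cv_res$folds, function(fd)
      identical(fd$hp$C, gs$hp$C) && identical(fd$hp$H, gs$hp$H) &&
        fd$hp$delta == gs$hp$delta &&
        all(unclass(fd$hp$weights) == unclass(gs$hp$weights)), logical(1))
    if (!all(same))
      warning(sum(!same), " fold(s) selected different hyperparameters; ",
              "their slopes are excluded from the mean")
    if (any(same)) {
      mean_slopes <- rbind(
        G = colMeans(do.call(rbind, lapply(cv_res$folds[same],
                                           `[[`, "slopes_G"))),
        B = colMeans(do.call(rbind, lapply(cv_res$folds[same],
                                           `[[`, "slopes_B"))))
      colnames(mean_slopes) <- colnames(f)
    }
  }
  structure(list(hp = gs$hp, model = model, fractions = f,
                 efficacies = efficacies, features = features,
                 fit_G = fit_g, fit_B = fit_b, cv = cv_res,
                 mean_slopes = mean_slopes, grid_loss = gs$loss,
                 call = match.call()),
            class = "conf_efficacy")
}

#' @export
print.conf_efficacy <- function(x, ...) {
  cat("Conformation-fraction efficacy model\n")
  w <- unclass(x$hp$weights)
  cat(sprintf("  selected: w = (%.3g, %.3g, %.3g), H = %d, delta = %g, C = %d\n",
              w[["theta"]], w[["C"]], w[["H"]], x$hp$H, x$hp$delta, x$hp$C))
  cat("  ligands:", nrow(x$fractions), " frames:",
      length(x$model$conf_labels), "\n")
  if (!is.null(x$cv)) {
    m <- x$cv$metrics
    cat(sprintf("  held-out: G MAE %.2f / RMSE %.2f / R2 %.3f;  B MAE %.2f / RMSE %.2f / R2 %.3f\n",
                m["G", "MAE"], m["G", "RMSE"], m["G", "R2"],
                m["B", "MAE"], m["B", "RMSE"], m["B", "R2"]))
  }
  invisible(x)
}

#' @export
coef.conf_efficacy <- function(object, ...) {
  out <- rbind(G = c(object$fit_G$intercept, object$fit_G$slopes),
               B = c(object$fit_B$intercept, object$fit_B$slopes))
  colnames(out) <- c("(Intercept)", colnames(object$fractions))
  out
}

#' @export
fitted.conf_efficacy <- function(object, ...) {
  cbind(G = object$fit_G$fitted, B = object$fit_B$fitted)
}

#' Residuals of a conformation-fraction efficacy model
#'
#' @param object a [conf_efficacy()] fit.
#' @param type `"training"` (full-fit residuals) or `"cv"` (held-out
#'   residuals from the outer leave-one-out protocol).
#' @param ... unused.
#' @return matrix with columns `G` and `B`.
#' @export
residuals.conf_efficacy <- function(object, type = c("training", "cv"), ...) {
  type <- match.arg(type)
  if (type == "training")
    return(cbind(G = object$fit_G$residuals, B = object$fit_B$residuals))
  if (is.null(object$cv)) stop("model was fitted with cv = FALSE")
  p <- object$cv$predictions
  cbind(G = p$obs_G - p$pred_G, B = p$obs_B - p$pred_B)
}

#' Predict efficacies for new ensembles or fraction rows
#'
#' New frames are assigned to the fitted conformations by nearest-medoid
#' extension and pooled into per-ligand fractions; alternatively, fraction
#' rows can be supplied directly.
#'
#' @param object a [conf_efficacy()] fit.
#' @param newdata a [frame_features()] object, or `NULL` for fitted values.
#' @param fractions ligand x conformation fraction matrix, overriding
#'   `newdata`.
#' @param ... unused.
#' @return matrix of predicted efficacies with columns `G` and `B`.
#' @export
predict.conf_efficacy <- function(object, newdata = NULL, fractions = NULL,
                                  ...) {
  if (is.null(fractions)) {
    if (is.null(newdata)) return(fitted(object))
    labels <- assign_frames(object$model, newdata, object$features)
    fractions <- compute_fractions(labels, newdata$ligand, object$hp$C)
  }
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1L)
  out <- cbind(G = predict(object$fit_G, fractions),
               B = predict(object$fit_B, fractions))
  rownames(out) <- rownames(fractions)
  out
}

#' Simulate efficacy tables from the fitted model
#'
#' Draws replicate efficacy tables from the fitted per-ligand means plus
#' Gaussian noise at each pathway's residual standard deviation.
#'
#' @param object a [conf_efficacy()] fit.
#' @param nsim number of replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of data.frames shaped like the training efficacy table.
#' @export
simulate.conf_efficacy <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  n <- nrow(mu)
  sd_g <- stats::sd(object$fit_G$residuals)
  sd_b <- stats::sd(object$fit_B$residuals)
  lapply(seq_len(nsim), function(s) {
    data.frame(ligand = object$efficacies$ligand,
               E_G = mu[, "G"] + stats::rnorm(n, 0, sd_g),
               E_B = mu[, "B"] + stats::rnorm(n, 0, sd_b),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' @export
summary.conf_efficacy <- function(object, ...) {
  slope_sd <- NULL
  if (!is.null(object$cv)) {
    sg <- do.call(rbind, lapply(object$cv$folds, `[[`, "slopes_G"))
    sb <- do.call(rbind, lapply(object$cv$folds, `[[`, "slopes_B"))
    if (ncol(sg) == object$hp$C)
      slope_sd <- rbind(G = apply(sg, 2L, stats::sd),
                        B = apply(sb, 2L, stats::sd))
  }
  structure(list(hp = object$hp, coef = coef(object),
                 mean_slopes = object$mean_slopes, slope_sd = slope_sd,
                 fractions = object$fractions,
                 metrics = if (!is.null(object$cv)) object$cv$metrics,
                 n_frames = length(object$model$conf_labels)),
            class = "summary.conf_efficacy")
}

#' @export
print.summary.conf_efficacy <- function(x, ...) {
  print(x$hp)
  cat("\nRegression coefficients (full fit):\n")
  print(round(x$coef, 3))
  if (!is.null(x$mean_slopes)) {
    cat("\nMean slopes across cross-validation folds:\n")
    print(round(x$mean_slopes, 3))
  }
  if (!is.null(x$metrics)) {
    cat("\nHeld-out performance:\n")
    print(round(x$metrics, 3))
  }
  cat("\nConformation fractions:\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Observed-versus-predicted plot
#'
#' Held-out (cross-validated) predictions against observed efficacies for
#' both pathways, with the identity line.
#'
#' @param x a [conf_efficacy()] fit (with `cv = TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.conf_efficacy <- function(x, ...) {
  if (is.null(x$cv)) stop("model was fitted with cv = FALSE")
  p <- x$cv$predictions
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (pw in c("G", "B")) {
    obs <- p[[paste0("obs_", pw)]]; prd <- p[[paste0("pred_", pw)]]
    lim <- range(obs, prd)
    graphics::plot(obs, prd, xlim = lim, ylim = lim,
                   xlab = "observed efficacy (%)",
                   ylab = "held-out predicted efficacy (%)",
                   main = paste("pathway", pw), ...)
    graphics::abline(0, 1, lty = 2, col = "grey40")
  }
  invisible(x)
}
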