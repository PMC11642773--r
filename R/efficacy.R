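# Efficacy regression on conformation fractions: minimum-norm least
# squares, inner leave-one-out loss, hyperparameter grid search, and the
# outer leave-one-out validation protocol.

#' Fit the per-pathway linear efficacy model
#'
#' Least-squares regression of efficacy on conformation fractions with an
#' intercept. Because fractions sum to one (collinear with the intercept)
#' and the system may be underdetermined, the minimum-norm least-squares
#' solution (SVD pseudoinverse) is returned: training residuals are the
#' least-squares optimum, but slopes are only unique up to the null
#' directions; predictions are unique.
#'
#' @param fractions training ligands x conformations fraction matrix.
#' @param efficacy numeric efficacy per training ligand.
#' @param intercept include an intercept (default `TRUE`).
#' @return object of class `mlr_fit`: `intercept`, `slopes`, `fitted`,
#'   `residuals`.
#' @export
fit_mlr <- function(fractions, efficacy, intercept = TRUE) {
  fractions <- as.matrix(fractions)
  if (!nrow(fractions)) stop("empty training set")
  if (nrow(fractions) != length(efficacy))
    stop("one efficacy per training ligand is required")
  X <- if (intercept) cbind(1, fractions) else fractions
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  pos <- sv$d > tol
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% efficacy) / sv$d[pos])
  beta <- drop(beta)
  fitted <- drop(X %*% beta)
  structure(list(intercept = if (intercept) beta[1L] else 0,
                 slopes = if (intercept) beta[-1L] else beta,
                 fitted = fitted, residuals = efficacy - fitted),
            class = "mlr_fit")
}

#' Predict efficacy from conformation fractions
#'
#' @param object an `mlr_fit`.
#' @param fractions fraction vector or matrix (rows = ligands).
#' @param ... unused.
#' @return predicted efficacy (numeric).
#' @export
predict.mlr_fit <- function(object, fractions, ...) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1L)
  if (ncol(fractions) != length(object$slopes))
    stop("fraction row length must equal the number of conformations")
  drop(object$intercept + fractions %*% object$slopes)
}

#' Inner leave-one-out loss
#'
#' Mean squared held-out error over sub-training splits: each training
#' ligand is held out in turn, the model is fit on the rest, and its squared
#' prediction error is averaged.
#'
#' @param fractions training ligands x conformations fraction matrix.
#' @param efficacy numeric efficacy per training ligand.
#' @return scalar mean squared error.
#' @export
inner_loo_loss <- function(fractions, efficacy) {
  fractions <- as.matrix(fractions)
  n <- nrow(fractions)
  if (n < 3L) stop("inner leave-one-out needs at least 3 training ligands")
  err2 <- vapply(seq_len(n), function(i) {
    fit <- fit_mlr(fractions[-i, , drop = FALSE], efficacy[-i])
    (efficacy[i] - predict(fit, fractions[i, ]))^2
  }, numeric(1))
  mean(err2)
}

#' The repaired component-weight grid
#'
#' Weight triples \eqn{(w_\theta, w_C, w_H)} built from
#' \eqn{w \in \{0.1, 0.2, 0.25, 0.33, 1\}} under the three patterns
#' `(w, w, 1-2w)`, `(w, 1-2w, w)`, `(1-2w, w, w)`, restricted to triples
#' with all entries nonnegative, plus the three pure triples `(1,0,0)`,
#' `(0,1,0)`, `(0,0,1)`. Duplicates are removed, first occurrence kept.
#'
#' @param w base weight values.
#' @return list of [distance_weights()] objects.
#' @export
default_weight_grid <- function(w = c(0.1, 0.2, 0.25, 0.33, 1)) {
  triples <- list()
  for (wi in w) {
    triples <- c(triples, list(c(wi, wi, 1 - 2 * wi),
                               c(wi, 1 - 2 * wi, wi),
                               c(1 - 2 * wi, wi, wi)))
  }
  triples <- c(triples, list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  triples <- Filter(function(t) all(t >= 0), triples)
  key <- vapply(triples, function(t) paste(sprintf("%.6f", t), collapse = ","),
                character(1))
  triples <- triples[!duplicated(key)]
  lapply(triples, function(t) distance_weights(t[1L], t[2L], t[3L]))
}

#' Hyperparameter grid
#'
#' All valid combinations of distance weights, hierarchical cluster count
#' `H`, bandwidth `delta` and conformation count `C` (kept where
#' `2 <= C <= H - 1`), ordered for the deterministic tie-break: smaller C,
#' then smaller H, then smaller delta, then weight-list order. The default
#' ranges are the full study grid; desk-scale runs pass narrower ones.
#'
#' @param weights list of [distance_weights()] (default
#'   [default_weight_grid()]).
#' @param H integer vector of hierarchical cluster counts.
#' @param delta numeric vector of bandwidths (Angstrom).
#' @param C integer vector of conformation counts, or `NULL` for the full
#'   range `2:(H-1)` per H.
#' @return object of class `efficacy_grid`.
#' @export
efficacy_grid <- function(weights = default_weight_grid(), H = 2:40,
                          delta = 1:3, C = NULL) {
  if (!length(weights)) stop("empty weight list")
  rows <- list()
  for (h in sort(unique(as.integer(H)))) {
    cs <- if (is.null(C)) seq(2L, h - 1L) else
      sort(unique(as.integer(C[C >= 2L & C <= h - 1L])))
    if (h < 3L || !length(cs)) next
    rows[[length(rows) + 1L]] <-
      expand.grid(C = cs, H = h, delta = as.numeric(delta),
                  w_idx = seq_along(weights))
  }
  if (!length(rows)) stop("hyperparameter grid is empty")
  g <- do.call(rbind, rows)
  g <- g[order(g$C, g$H, g$delta, g$w_idx), c("w_idx", "H", "delta", "C")]
  rownames(g) <- NULL
  structure(list(combos = g, weights = weights), class = "efficacy_grid")
}

#' @export
print.efficacy_grid <- function(x, ...) {
  cat("Hyperparameter grid:", nrow(x$combos), "points (",
      length(x$weights), "weight triples, H in",
      paste(range(x$combos$H), collapse = ".."), ", delta in {",
      paste(unique(x$combos$delta), collapse = ", "), "}, C in",
      paste(range(x$combos$C), collapse = ".."), ")\n")
  invisible(x)
}

grid_hp <- function(grid, i) {
  g <- grid$combos[i, ]
  hyperparameters(grid$weights[[g$w_idx]], g$H, g$delta, g$C)
}

# Cache of clustering artifacts shared across grid points and CV folds.
# Clustering is unsupervised (it never sees efficacies), so one fit per
# hyperparameter point serves every fold.
cluster_cache <- function(features, stride = 1L, subsample = NULL) {
  idx <- subsample %||% seq(1L, n_frames(features), by = as.integer(stride))
  sub <- features[idx]
  env <- new.env(parent = emptyenv())
  env$wcache <- list()  # per weight triple: distance matrices + hclust tree
  env$mcache <- list()  # per full hyperparameter point: conformation model

  get_weights <- function(w) {
    key <- paste(sprintf("%.8f", unclass(w)), collapse = ",")
    if (is.null(env$wcache[[key]])) {
      dm <- frame_distances(sub, w)
      hc <- stats::hclust(stats::as.dist(dm$D), method = "complete")
      env$wcache[[key]] <- list(dm = dm, hc = hc, cuts = list(),
                                rmsd = list())
    }
    env$wcache[[key]]
  }
  get_model <- function(hp) {
    key <- paste(sprintf("%.8f", unclass(hp$weights)), hp$H, hp$delta, hp$C,
                 sep = "|", collapse = ",")
    if (is.null(env$mcache[[key]])) {
      wc <- get_weights(hp$weights)
      env$mcache[[key]] <- tryCatch(
        finish_conformation_model(features, hp, idx, wc$dm, wc$hc),
        confeff_empty_conformation = function(e) e)
    }
    env$mcache[[key]]
  }
  list(get_model = get_model, idx = idx)
}

#' Grid search over clustering hyperparameters
#'
#' Scores every grid point by the sum of the two pathways' inner
#' leave-one-out losses on the training ligands and returns the minimizer.
#' A point whose spectral assignment leaves a conformation empty is scored
#' infeasible (infinite loss). Ties break deterministically toward the
#' simpler model: smaller C, then H, then delta, then weight order.
#'
#' @param features full [frame_features()] set (clustering is unsupervised
#'   and uses all ligands' frames).
#' @param efficacies data.frame with `ligand`, `E_G`, `E_B`.
#' @param training_ligands ligand labels making up the training set.
#' @param grid an [efficacy_grid()].
#' @param stride clustering subsample stride.
#' @param cache optional shared cache from previous calls (internal).
#' @return list: `hp` (selected [hyperparameters()]), `loss` (its summed
#'   loss), `losses` (all grid points), `model` (its conformation model).
#' @export
grid_search <- function(features, efficacies, training_ligands, grid,
                        stride = 1L, cache = NULL) {
  stopifnot(inherits(grid, "efficacy_grid"))
  cache <- cache %||% cluster_cache(features, stride)
  eg <- efficacies$E_G[match(training_ligands, efficacies$ligand)]
  eb <- efficacies$E_B[match(training_ligands, efficacies$ligand)]
  if (anyNA(eg) || anyNA(eb))
    stop("missing efficacy for ligand(s): ",
         paste(training_ligands[is.na(eg) | is.na(eb)], collapse = ", "))
  np <- nrow(grid$combos)
  losses <- numeric(np)
  for (i in seq_len(np)) {
    hp <- grid_hp(grid, i)
    model <- cache$get_model(hp)
    if (inherits(model, "condition")) { losses[i] <- Inf; next }
    f <- model$fractions[training_ligands, , drop = FALSE]
    losses[i] <- inner_loo_loss(f, eg) + inner_loo_loss(f, eb)
  }
  if (all(!is.finite(losses))) stop("all grid points are infeasible")
  best <- which.min(losses)  # first minimum = tie-break order
  list(hp = grid_hp(grid, best), loss = losses[best], losses = losses,
       model = cache$get_model(grid_hp(grid, best)))
}

#' Outer leave-one-out cross-validation
#'
#' For each ligand in turn: run the hyperparameter grid search on the
#' remaining ligands (with the inner leave-one-out loss), fit both
#' pathways' regressions on them, and predict the held-out ligand. The
#' held-out efficacy is never seen by its own fold. Aggregates MAE, RMSE
#' and the coefficient of determination per pathway and stores per-fold
#' slopes and selected hyperparameters for the response-function stage.
#'
#' @inheritParams grid_search
#' @return object of class `efficacy_cv`: `predictions` (data.frame),
#'   `metrics`, `folds` (per-fold hyperparameters and slopes).
#' @export
outer_loo_cv <- function(features, efficacies, grid, stride = 1L,
                         cache = NULL) {
  ligs <- efficacies$ligand
  if (length(ligs) < 4L) stop("outer leave-one-out needs at least 4 ligands")
  if (!all(ligs %in% features$ligand))
    stop("no frames for ligand(s): ",
         paste(setdiff(ligs, features$ligand), collapse = ", "))
  cache <- cache %||% cluster_cache(features, stride)
  folds <- vector("list", length(ligs))
  pred <- data.frame(ligand = ligs, obs_G = efficacies$E_G,
                     obs_B = efficacies$E_B, pred_G = NA_real_,
                     pred_B = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ligs)) {
    train <- ligs[-i]
    gs <- grid_search(features, efficacies, train, grid, stride, cache)
    f_train <- gs$model$fractions[train, , drop = FALSE]
    fit_g <- fit_mlr(f_train, efficacies$E_G[-i])
    fit_b <- fit_mlr(f_train, efficacies$E_B[-i])
    f_test <- gs$model$fractions[ligs[i], ]
    pred$pred_G[i] <- predict(fit_g, f_test)
    pred$pred_B[i] <- predict(fit_b, f_test)
    folds[[i]] <- list(ligand = ligs[i], hp = gs$hp, loss = gs$loss,
                       slopes_G = fit_g$slopes, slopes_B = fit_b$slopes,
                       intercept_G = fit_g$intercept,
                       intercept_B = fit_b$intercept)
  }
  metric <- function(obs, prd) {
    c(MAE = mean(abs(obs - prd)),
      RMSE = sqrt(mean((obs - prd)^2)),
      R2 = 1 - sum((obs - prd)^2) / sum((obs - mean(obs))^2))
  }
  structure(list(predictions = pred,
                 metrics = rbind(G = metric(pred$obs_G, pred$pred_G),
                                 B = metric(pred$obs_B, pred$pred_B)),
                 folds = folds, grid = grid),
            class = "efficacy_cv")
}

#' @export
print.efficacy_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation over", nrow(x$predictions),
      "ligands\n")
  m <- x$metrics
  cat(sprintf("  G pathway: MAE %.2f  RMSE %.2f  R2 %.3f\n",
              m["G", "MAE"], m["G", "RMSE"], m["G", "R2"]))
  cat(sprintf("  B pathway: MAE %.2f  RMSE %.2f  R2 %.3f\n",
              m["B", "MAE"], m["B", "RMSE"], m["B", "R2"]))
  hps <- vapply(x$folds, function(f)
    sprintf("C=%d,H=%d,d=%g", f$hp$C, f$hp$H, f$hp$delta), character(1))
  cat("  selected hyperparameters:",
      paste(sprintf("%s (%d fold%s)", names(table(hps)), table(hps),
                    ifelse(table(hps) > 1, "s", "")), collapse = "; "), "\n")
  invisible(x)
}
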