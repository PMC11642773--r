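# Efficacy regression and the nested leave-one-out protocol.

test_that("minimum-norm least squares interpolates and recovers the model", {
  # one-hot rows, no intercept: slopes are the efficacies themselves
  f <- diag(3)
  e <- c(20, 60, 95)
  fit0 <- fit_mlr(f, e, intercept = FALSE)
  expect_equal(unname(fit0$slopes), e)

  # noiseless forward model with more independent ligands than parameters:
  # predictions match exactly even though slopes are only unique up to the
  # intercept/sum-to-one null direction
  set.seed(5)
  F10 <- confeff:::rdirichlet(10, rep(1, 4))
  beta <- c(15, 80, 40, -10, 5)
  y <- beta[1] + drop(F10 %*% beta[-1])
  fit <- fit_mlr(F10, y)
  expect_lt(max(abs(predict(fit, F10) - y)), 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)

  # duplicated rows are equivalent to doubling the weight of one row;
  # oracle: weighted lm (QR route, independent of the SVD pseudoinverse)
  yn <- y + rnorm(10, 0, 3)
  Fd <- rbind(F10, F10[3, ]); yd <- c(yn, yn[3])
  fit_dup <- fit_mlr(Fd, yd)
  w <- rep(1, 10); w[3] <- 2
  wfit <- lm(yn ~ F10, weights = w)
  expect_equal(unname(predict(fit_dup, F10)), unname(fitted(wfit)),
               tolerance = 1e-6)

  expect_error(fit_mlr(matrix(numeric(0), 0, 2), numeric(0)), "empty")
})

test_that("prediction is affine in the fractions", {
  set.seed(6)
  fit <- fit_mlr(confeff:::rdirichlet(8, rep(1, 3)), rnorm(8, 50, 20))
  expect_equal(unname(predict(fit, c(0, 0, 0))), fit$intercept)
  f1 <- c(0.2, 0.5, 0.3); f2 <- c(0.7, 0.1, 0.2)
  expect_lt(abs(predict(fit, f1) + predict(fit, f2) -
                  2 * predict(fit, (f1 + f2) / 2)), 1e-10)
  # hand evaluation
  fit2 <- structure(list(intercept = 0, slopes = c(100, 50)),
                    class = "mlr_fit")
  expect_equal(unname(predict(fit2, c(0.2, 0.8))), 60)
  expect_error(predict(fit2, c(1, 0, 0)), "length")
})

test_that("the inner leave-one-out loss behaves as a mean of fold errors", {
  set.seed(7)
  F6 <- confeff:::rdirichlet(6, rep(1, 2))
  beta <- c(10, 50, -20)
  y <- beta[1] + drop(F6 %*% beta[-1])
  expect_lt(inner_loo_loss(F6, y), 1e-10)          # exact model class
  expect_lt(inner_loo_loss(F6, rep(42, 6)), 1e-10) # intercept-only solution
  # invariance under ligand reordering
  yn <- y + rnorm(6, 0, 5)
  p <- sample(6)
  expect_equal(inner_loo_loss(F6, yn), inner_loo_loss(F6[p, ], yn[p]))
  expect_error(inner_loo_loss(F6[1:2, ], yn[1:2]), "at least 3")
})

test_that("the repaired weight grid keeps exactly the valid printed triples", {
  g <- default_weight_grid()
  tr <- t(vapply(g, unclass, numeric(3)))
  expect_true(all(abs(rowSums(tr) - 1) < 1e-12))
  expect_true(all(tr >= 0))
  # the reported optimum and the pure triples are present
  has <- function(w) any(apply(tr, 1, function(r) all(abs(r - w) < 1e-9)))
  expect_true(has(c(0.25, 0.25, 0.5)))
  expect_true(has(c(0.5, 0.25, 0.25)))
  expect_true(has(c(1, 0, 0)) && has(c(0, 1, 0)) && has(c(0, 0, 1)))
  # w = 1 under the mixed patterns would be negative: excluded
  expect_false(has(c(1, 1, -1)))
  expect_false(any(tr < 0))
  expect_equal(anyDuplicated(round(tr, 9)), 0L)
})

test_that("grid search minimizes the summed loss with a deterministic tie-break", {
  st <- synthetic_study(n_templates = 3, n_ligands = 8,
                        n_frames_per_ligand = 150, n_replicas = 1, seed = 14)
  one <- efficacy_grid(weights = list(distance_weights(1/3, 1/3, 1/3)),
                       H = 6, delta = 2, C = 3)
  gs1 <- grid_search(st$features, st$efficacies, st$efficacies$ligand, one,
                     stride = 3)
  expect_equal(gs1$hp$C, 3L)  # a one-point grid returns that point

  # planted point at C = 3 beats an under-split alternative
  grid <- efficacy_grid(weights = list(distance_weights(1/3, 1/3, 1/3)),
                        H = 6, delta = 2, C = c(2, 3))
  gs <- grid_search(st$features, st$efficacies, st$efficacies$ligand, grid,
                    stride = 3)
  expect_equal(gs$hp$C, 3L)
  expect_equal(gs$losses[which.min(gs$losses)], gs$loss)

  # adding a strictly dominated point never changes the selection
  grid2 <- efficacy_grid(weights = list(distance_weights(1/3, 1/3, 1/3)),
                         H = c(6, 7), delta = 2, C = c(2, 3))
  gs2 <- grid_search(st$features, st$efficacies, st$efficacies$ligand, grid2,
                     stride = 3)
  expect_equal(gs2$loss, min(gs2$losses))
  expect_lte(gs2$loss, gs$loss + 1e-9)

  # grid ordering implements the simpler-model tie-break
  expect_equal(grid2$combos$C, sort(grid2$combos$C))
})

test_that("outer leave-one-out is exact on noiseless linear data", {
  st <- synthetic_study(n_templates = 3, n_ligands = 8,
                        n_frames_per_ligand = 100, n_replicas = 1,
                        torsion_kappa = Inf, coord_sigma = 0,
                        hbond_sigma = 0, efficacy_noise_sd = 0, seed = 15)
  # efficacies exactly linear in the empirical fractions
  emp <- compute_fractions(st$features$template, st$features$ligand, 3)
  eff <- data.frame(ligand = rownames(emp),
                    E_G = 5 + drop(emp %*% c(90, 40, -10)),
                    E_B = -3 + drop(emp %*% c(10, 80, 30)))
  grid <- efficacy_grid(weights = list(distance_weights(1/3, 1/3, 1/3)),
                        H = 5, delta = 2, C = 3)
  cv <- outer_loo_cv(st$features, eff, grid, stride = 2)
  expect_lt(cv$metrics["G", "MAE"], 1e-6)
  expect_lt(cv$metrics["B", "MAE"], 1e-6)
  expect_equal(length(cv$folds), 8L)
})

test_that("held-out RMSE is calibrated to the efficacy noise", {
  set.seed(77)
  sigma <- 4
  F12 <- confeff:::rdirichlet(12, rep(1, 3))
  beta <- c(10, 70, 30, -20)
  mu <- beta[1] + drop(F12 %*% beta[-1])
  rmses <- vapply(1:50, function(s) {
    set.seed(s)
    y <- mu + rnorm(12, 0, sigma)
    prd <- vapply(1:12, function(i)
      predict(fit_mlr(F12[-i, ], y[-i]), F12[i, ]), numeric(1))
    sqrt(mean((y - prd)^2))
  }, numeric(1))
  expect_true(all(rmses > 0.5 * sigma))
  expect_true(all(rmses < 3 * sigma))
})
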