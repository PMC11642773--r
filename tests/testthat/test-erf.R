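# Densities, efficacy response functions, activation functions and scores.

test_that("periodic density integrates to one and preserves seam mass", {
  grid <- confeff:::erf_grid(c(-pi, pi))
  sp <- diff(grid[1:2])

  # uniform on the circle: flat at 1/(2pi) within Monte-Carlo error
  set.seed(3)
  d <- periodic_density(runif(200000, -pi, pi))
  vals <- d$eval(grid)
  expect_lt(abs(step_integral(d, c(-pi, pi)) - 1), 1e-6)
  # sup deviation bounded by ~5 binomial SEs of a 5-degree bin
  se <- sqrt((1 / 72) * (1 - 1 / 72) / 200000) / (2 * pi / 72)
  expect_lt(max(abs(vals - 1 / (2 * pi))), 5 * se)

  # point mass just inside +pi: triplication spreads mass to both seam sides
  x0 <- 179.9 * pi / 180
  dp <- periodic_density(rep(x0, 100))
  vp <- dp$eval(grid)
  expect_lt(abs(step_integral(dp, c(-pi, pi)) - 1), 1e-6)
  expect_gt(max(vp[grid < -3.1]), 0)  # mass at the -pi side of the seam
  expect_gt(max(vp[grid > 3.1]), 0)   # and at the +pi side
  expect_equal(sum(vp > 0) * sp < 0.2, TRUE)  # still concentrated

  # normalization holds for arbitrary inputs
  for (s in 1:3) {
    set.seed(s)
    dd <- periodic_density(rvonmises(500, runif(1, -pi, pi), 5))
    expect_lt(abs(step_integral(dd, c(-pi, pi)) - 1), 1e-6)
  }
  expect_error(periodic_density(numeric(0)), "empty")
})

test_that("linear density matches an independent binning oracle", {
  dom <- c(0, 10)
  grid <- confeff:::erf_grid(dom)
  sp <- diff(grid[1:2])
  set.seed(9)
  x <- c(rnorm(4000, 3, 0.5), rnorm(6000, 7, 0.8))
  x <- x[x > 0 & x < 10]
  d <- linear_density(x, n_bins = 50, domain = dom)
  expect_lt(abs(step_integral(d, dom) - 1), 1e-6)
  # oracle: hist() with the same equal-width bins
  h <- hist(x, breaks = seq(0, 10, length.out = 51), plot = FALSE)
  expect_equal(d$density, h$density, tolerance = 1e-12)

  # uniform deterministic samples -> 1/|domain|
  u <- linear_density(rep(seq(0.5, 9.5, by = 1), each = 100), n_bins = 10,
                      domain = dom)
  expect_equal(u$eval(c(1, 5, 9)), rep(1 / 10, 3))
  expect_error(linear_density(c(1, 11), domain = dom), "outside")
})

test_that("response functions weight densities by slopes", {
  grid <- seq(0, 3, length.out = 1000)
  supp1 <- seq(0.005, 0.995, length.out = 100)
  supp2 <- seq(2.005, 2.995, length.out = 100)
  r <- erf_response(list(supp1, supp2), c(2, -1), grid, periodic = FALSE,
                    n_bins = 30, domain = c(0, 3))
  mid1 <- grid > 0.15 & grid < 0.85
  mid2 <- grid > 2.15 & grid < 2.85
  gap <- grid > 1.15 & grid < 1.85
  expect_equal(unique(round(r[mid1], 9)), 2)
  expect_equal(unique(round(r[mid2], 9)), -1)
  expect_equal(unique(r[gap]), 0)

  # identical densities with opposite slopes cancel
  r0 <- erf_response(list(supp1, supp1), c(3, -3), grid, periodic = FALSE,
                     n_bins = 30, domain = c(0, 3))
  expect_equal(max(abs(r0)), 0)

  # single conformation with unit slope returns its density
  r1 <- erf_response(list(supp1), 1, grid, periodic = FALSE, n_bins = 30,
                     domain = c(0, 3))
  d1 <- linear_density(supp1, n_bins = 30, domain = c(0, 3))
  expect_equal(r1, d1$eval(grid))

  # conformation without samples is excluded with a warning
  expect_warning(
    erf_response(list(supp1, numeric(0)), c(1, 5), grid, periodic = FALSE,
                 n_bins = 30, domain = c(0, 3)),
    "slope mass 5")
})

test_that("activation functions implement the sign truth tables", {
  expect_equal(general_activation(3, 2), 2)
  expect_equal(general_activation(-3, -2), 2)
  expect_equal(general_activation(3, -2), 0)
  expect_equal(general_activation(0, 5), 0)    # zero is neither sign
  expect_equal(selective_activation(1, -2), 3)
  expect_equal(selective_activation(-1, 2), 3)
  expect_equal(selective_activation(1, 2), 0)
  expect_equal(selective_activation(-1, 0), 0)

  # exclusivity: a and s never simultaneously nonzero
  set.seed(12)
  rg <- rnorm(1000); rb <- rnorm(1000)
  a <- general_activation(rg, rb); s <- selective_activation(rg, rb)
  expect_true(all(a * s == 0))
  expect_true(all(a >= 0) && all(s >= 0))

  # scaling both responses scales both activation functions linearly
  lam <- 2.7
  expect_equal(general_activation(lam * rg, lam * rb), lam * a)
  expect_equal(selective_activation(lam * rg, lam * rb), lam * s)
})

test_that("the Riemann score matches closed-form integrals", {
  dom <- c(-1, 3)
  grid <- confeff:::erf_grid(dom)
  expect_equal(activation_score(rep(2.5, 1000), grid), 2.5 * 4,
               tolerance = 2 / 999)
  expect_equal(activation_score(rep(0, 1000), grid), 0)
  # triangle of base 4 and height 2: area 4
  tri <- pmax(0, 2 - abs(grid - 1))
  expect_equal(activation_score(tri, grid), 4, tolerance = 0.002 * 4)
  expect_error(activation_score(1:3, c(0, 1, 3)), "uniformly spaced")
})

test_that("features identical across conformations score zero under zero-sum slopes", {
  set.seed(21)
  x <- rnorm(3000, 0, 0.5)
  samples <- list(x, x, x)
  grid <- confeff:::erf_grid(c(-pi, pi))
  slopes <- c(2, -1.5, -0.5)  # sums to zero
  r <- erf_response(samples, slopes, grid, periodic = TRUE)
  expect_lt(max(abs(r)), 1e-9)
  a <- general_activation(r, r); s <- selective_activation(r, r)
  expect_equal(activation_score(a, grid), 0)
  expect_equal(activation_score(s, grid), 0)
})
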