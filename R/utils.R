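# Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles onto [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped to the half-open interval \eqn{[-\pi, \pi)}.
#'   Entries already in range are returned bit-identically.
#' @export
wrap_angle <- function(x) {
  out_of_range <- x < -pi | x >= pi
  if (any(out_of_range))
    x[out_of_range] <- ((x[out_of_range] + pi) %% (2 * pi)) - pi
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Draw von Mises distributed angles
#'
#' Rejection sampler of Best and Fisher (1979). `kappa = Inf` returns the
#' means exactly (zero-noise limit); `kappa = 0` is uniform on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction(s), radians; recycled to length `n`.
#' @param kappa concentration (>= 0, may be `Inf`).
#' @return `n` angles in \eqn{[-\pi, \pi)}.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  mu <- rep_len(mu, n)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(wrap_angle(mu))
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + k
    }
  }
  wrap_angle(mu + out)
}

# Dirichlet rows (used for synthetic mixture weights).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, ncol = k, byrow = TRUE)
  g / rowSums(g)
}

# Consistent error helper carrying a subclass usable with tryCatch().
confeff_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
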