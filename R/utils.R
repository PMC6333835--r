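## Circular helpers shared across modules.  All phases are radians in
## [-pi, pi) with 0 at the signal maximum (cosine convention); degrees are
## used only at user-facing boundaries.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Wrap angles into [-pi, pi)
#' @param x angles in radians
#' @return wrapped angles
#' @keywords internal
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% can return exactly pi for inputs like -pi - eps due to rounding
  y[y >= pi] <- y[y >= pi] - 2 * pi
  y
}

wrap_360 <- function(deg) deg %% 360

#' Smallest absolute circular difference in degrees
#' @keywords internal
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of angles in radians
#' @keywords internal
circ_mean <- function(x) Arg(sum(exp(1i * x)))

#' Circular correlation coefficient (Fisher & Lee)
#' @keywords internal
circ_cor <- function(a, b) {
  num <- sum(sin(a - mean_dir(a)) * sin(b - mean_dir(b)))
  den <- sqrt(sum(sin(a - mean_dir(a))^2) * sum(sin(b - mean_dir(b))^2))
  num / den
}

mean_dir <- function(x) Arg(sum(exp(1i * x)))

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; reduces to uniform angles at
#' `kappa = 0`.
#'
#' @param n number of draws
#' @param mu mean direction, radians
#' @param kappa concentration (>= 0)
#' @return angles in [-pi, pi)
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-9) return(wrap_pi(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(out + mu)
}

## Derive a stream of child seeds from one user seed; keeps every derived
## seed a valid 32-bit integer.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
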