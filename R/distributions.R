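#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. Used for turning angles of both
#' simulated agents and the random-step sampler.
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (`>= 0`); `kappa = 0` gives the circular uniform.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    m <- n - i + 1L
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[i:(i + k - 1L)] <- theta
      i <- i + k
    }
  }
  wrap_angle(out + mu)
}

#' von Mises density
#' @inheritParams rvonmises
#' @param x angles (rad).
#' @export
dvonmises <- function(x, mu = 0, kappa = 1) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE) * exp(kappa))
}

# Mean-resultant-length equation A1(kappa) = I1/I0; solved for the MLE.
vm_A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood fit of a von Mises distribution
#'
#' Closed-form mean direction; concentration solves `A1(kappa) = Rbar`
#' numerically. Nearly-degenerate samples (all angles equal) drive the MLE to
#' infinity; the estimate is capped at `kappa_max` with a warning.
#'
#' @param theta angles (rad).
#' @param kappa_max cap on the fitted concentration.
#' @return list with `mu`, `kappa`, `Rbar`, `n`.
#' @export
fit_vonmises <- function(theta, kappa_max = 500) {
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n < 2) stop("need at least 2 finite angles")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  mu <- atan2(S, C)
  Rbar <- sqrt(C^2 + S^2)
  if (Rbar >= vm_A1(kappa_max)) {
    warning("turning angles nearly degenerate; kappa capped at ", kappa_max)
    kappa <- kappa_max
  } else if (Rbar < 1e-8) {
    kappa <- 0
  } else {
    kappa <- uniroot(function(k) vm_A1(k) - Rbar, c(1e-8, kappa_max),
                     tol = 1e-10)$root
  }
  list(mu = mu, kappa = kappa, Rbar = Rbar, n = n)
}
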