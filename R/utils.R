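# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is half-open at the left
  y[y <= -pi] <- pi
  y
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' von Mises density
#'
#' Circular density with mean `mu` and concentration `kappa`, evaluated with
#' exponentially scaled Bessel functions so large concentrations stay finite.
#'
#' @param x angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, > 0 (0 gives the circular uniform).
#' @param log if TRUE return the log density.
#' @return density (or log density) values.
#' @export
dvonmises <- function(x, mu, kappa, log = FALSE) {
  stopifnot(all(kappa >= 0))
  ld <- kappa * (cos(x - mu) - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to the circular uniform when
#' `kappa` is (numerically) zero.
#'
#' @param n number of draws.
#' @param mu mean direction (radians); scalar or length-n.
#' @param kappa concentration, scalar.
#' @return n angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(stats::runif(1) - 0.5) * acos(max(-1, min(1, f)))
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# Weighted z-score constants; guards degenerate (constant) series.
standardize_constants <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) s <- 1
  c(mean = m, sd = s)
}

apply_standardize <- function(x, const) (x - const[["mean"]]) / const[["sd"]]

# Deterministic integer sub-seed derived from a master seed; stays < 2^31.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 9973L
}

# fast row-wise maximum for matrices with few columns
row_max <- function(M) {
  out <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) out <- pmax(out, M[, j])
  out
}
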