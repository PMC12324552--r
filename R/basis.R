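# Raised-cosine temporal basis used by every sensory and history kernel.
#
# A kernel is stored as a short coefficient vector over the basis; the
# realized lag weights (one weight per time lag 1..n_lag) are the basis
# matrix times the coefficients.

#' Raised-cosine temporal basis
#'
#' Builds an `n_lag` x `n_basis` matrix of raised-cosine bumps with linearly
#' spaced centers spanning lags 1..`n_lag`. Adjacent bumps overlap so smooth
#' kernels (derivative- or integrator-shaped) are representable with few
#' coefficients.
#'
#' @param n_basis number of basis functions (default 4).
#' @param n_lag history length in time steps (default 14, about 5 s at the
#'   default step of 5/14 s).
#' @return list with `n_basis`, `n_lag` and the basis matrix `Phi`
#'   (`n_lag` rows, `n_basis` columns), of class `stapaw_basis`.
#' @export
stapaw_basis <- function(n_basis = 4, n_lag = 14) {
  stopifnot(n_basis >= 1, n_lag >= 1, n_basis <= n_lag)
  lags <- seq_len(n_lag)
  if (n_basis == 1) {
    centers <- mean(range(lags))
    width <- n_lag
  } else {
    centers <- seq(1, n_lag, length.out = n_basis)
    width <- 2 * (centers[2] - centers[1])
  }
  Phi <- sapply(centers, function(ck) {
    d <- lags - ck
    ifelse(abs(d) < width, 0.5 * (1 + cos(pi * d / width)), 0)
  })
  Phi <- matrix(Phi, nrow = n_lag, ncol = n_basis)
  structure(list(n_basis = n_basis, n_lag = n_lag, Phi = Phi),
            class = "stapaw_basis")
}

#' Realized lag weights of a kernel
#'
#' @param coef coefficient vector over the basis.
#' @param basis a [stapaw_basis()] object.
#' @return numeric vector of length `basis$n_lag`; entry l is the weight on
#'   the input l steps in the past.
#' @export
realized_weights <- function(coef, basis) {
  stopifnot(length(coef) == basis$n_basis)
  drop(basis$Phi %*% coef)
}

# Basis-convolved design matrix for one covariate series.
# X[t, k] = sum_{l=1..L} Phi[l, k] * x[t - l], with x zero-padded before the
# first sample (the series is expected to be standardized already, so zeros
# correspond to the dataset mean).
lag_design <- function(x, basis) {
  L <- basis$n_lag
  Tn <- length(x)
  xp <- c(rep(0, L), x)
  X <- matrix(0, nrow = Tn, ncol = basis$n_basis)
  for (k in seq_len(basis$n_basis)) {
    y <- stats::filter(xp, basis$Phi[, k], method = "convolution", sides = 1)
    X[, k] <- y[L:(L + Tn - 1)]
  }
  X[!is.finite(X)] <- 0
  X
}

# Least-squares projection of a target lag profile onto the basis span.
# With zero_sum = TRUE the coefficients are additionally corrected so the
# realized weights sum to zero (a pure trend detector: the filtered signal
# is insensitive to the standing input level).
project_to_basis <- function(target, basis, zero_sum = FALSE) {
  stopifnot(length(target) == basis$n_lag)
  Phi <- basis$Phi
  coef <- drop(solve(crossprod(Phi), crossprod(Phi, target)))
  if (zero_sum) {
    s <- colSums(Phi)
    coef <- coef - s * sum(s * coef) / sum(s * s)
  }
  coef
}

# Filtered value for a single history vector given recent-first ordering:
# hist[l] is the (standardized) input l steps back. Short histories are
# zero-padded at the old end.
filter_history <- function(hist, coef, basis) {
  L <- basis$n_lag
  h <- rep(0, L)
  n <- min(L, length(hist))
  if (n > 0) h[seq_len(n)] <- hist[seq_len(n)]
  sum(realized_weights(coef, basis) * h)
}
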