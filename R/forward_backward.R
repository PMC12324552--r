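# E-step machinery: forward-backward decoding and hard state paths.

#' Forward-backward decoding of one track
#'
#' Runs the scaled forward-backward recursion under per-step input-driven
#' transition matrices and returns the posterior state marginals, pairwise
#' posteriors, and the exact marginal log-likelihood of the track.
#'
#' @param params a `stapaw_params` object.
#' @param track a `stapaw_track` with sensory series.
#' @return an object of class `stapaw_decode`: list with `gamma` (T x Z),
#'   `xi` ((T-1) x Z^2, column-major over state pairs), and `loglik`.
#' @export
forward_backward <- function(params, track) {
  design <- stapaw_design(track, params)
  logB <- emission_loglik_design(params, design)
  A <- transition_array(params, design)      # T x Z x Z
  fb_raw(logB, aperm(A, c(2, 3, 1)), params$init_dist)
}

#' Forward-backward on raw matrices
#'
#' Low-level entry point used for testing against exhaustive path
#' enumeration: takes an arbitrary emission log-likelihood matrix,
#' transition array and initial distribution.
#'
#' @param logB T x Z emission log-likelihood matrix.
#' @param A Z x Z x T array of transition matrices; slice t governs
#'   `z[t-1] -> z[t]` (slice 1 is unused).
#' @param pi initial state distribution.
#' @return list with `gamma`, `xi`, `loglik` (class `stapaw_decode`).
#' @export
fb_raw <- function(logB, A, pi) {
  stopifnot(length(dim(A)) == 3, dim(A)[1] == ncol(logB),
            dim(A)[2] == ncol(logB), dim(A)[3] == nrow(logB))
  out <- .fb_cpp(logB, A, pi)
  structure(out, class = "stapaw_decode")
}

#' @export
print.stapaw_decode <- function(x, ...) {
  cat(sprintf("<stapaw decode: %d steps, %d states, loglik %.3f>\n",
              nrow(x$gamma), ncol(x$gamma), x$loglik))
  invisible(x)
}

#' Decode latent states of a track
#'
#' @param params fitted `stapaw_params`.
#' @param track a `stapaw_track`.
#' @param method `"marginal"` (per-step argmax of the posterior marginals;
#'   ties break toward the lower state index) or `"viterbi"`.
#' @return list with `states` (integer path) and `gamma` (marginals).
#' @export
decode_states <- function(params, track, method = c("marginal", "viterbi")) {
  method <- match.arg(method)
  dec <- forward_backward(params, track)
  states <- if (method == "viterbi") {
    viterbi_path(params, track)
  } else {
    apply(dec$gamma, 1, which.max)  # which.max takes the first (lowest) index
  }
  list(states = as.integer(states), gamma = dec$gamma, loglik = dec$loglik)
}

viterbi_path <- function(params, track) {
  design <- stapaw_design(track, params)
  logB <- emission_loglik_design(params, design)
  A <- transition_array(params, design)
  Tn <- nrow(logB); Z <- ncol(logB)
  delta <- log(params$init_dist) + logB[1, ]
  psi <- matrix(0L, Tn, Z)
  for (t in 2:Tn) {
    lA <- log(A[t, , , drop = FALSE])
    dim(lA) <- c(Z, Z)
    cand <- delta + lA  # cand[i, j]
    psi[t, ] <- apply(cand, 2, which.max)
    delta <- apply(cand, 2, max) + logB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
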