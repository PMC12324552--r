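# Probability computations of the staPAW model: input-driven transition
# matrices, turn decisions, heading-change and speed densities, and the
# per-step emission log-likelihood matrix.
#
# Time conventions: a track stores per-step observations (dtheta_t, dr_t,
# C_t, dCp_t). All kernels act on strictly past input, so the filtered
# covariates at step t are built from lags t-1 .. t-L (zero-padded, after
# standardization, before the track start). The transition matrix "at t"
# governs z_{t-1} -> z_t.

DR_FLOOR <- 1e-4  # cm; stationary frames are floored before Gamma evaluation

# Build the filtered design for one track under a parameter set: basis-
# convolved standardized C, |dtheta|, standardized dCp, and optional I.
stapaw_design <- function(track, params) {
  basis <- params$basis
  Cs <- apply_standardize(track$C, params$standardize$C)
  dCps <- apply_standardize(track$dCp, params$standardize$dCp)
  list(
    X_C = lag_design(Cs, basis),
    X_h = lag_design(abs(track$dtheta), basis),
    X_dCp = lag_design(dCps, basis),
    X_O = if (!is.null(track$I)) lag_design(as.numeric(track$I), basis)
          else NULL,
    dtheta = track$dtheta,
    dr = pmax(track$dr, DR_FLOOR),
    n = track_length(track))
}

# Per-step transition logits/matrices for a whole design: returns a T x Z x Z
# array A with A[t, i, j] = P(z_t = j | z_{t-1} = i).
transition_array <- function(params, design) {
  Z <- params$Z
  Tn <- design$n
  tr <- params$transition
  A <- array(0, dim = c(Tn, Z, Z))
  if (Z == 1) { A[, 1, 1] <- 1; return(A) }
  logits <- array(0, dim = c(Tn, Z, Z))
  for (i in seq_len(Z)) {
    logits[, i, i] <- tr$baseline[i]
    for (j in seq_len(Z)) {
      if (i == j) next
      k <- tr$kernels[[i]][[j]]
      v <- drop(design$X_C %*% k)
      if (!is.null(tr$opto) && !is.null(design$X_O)) {
        o <- tr$opto[[i]][[j]]
        if (!is.null(o)) v <- v + drop(design$X_O %*% o)
      }
      logits[, i, j] <- v
    }
  }
  if (!all(is.finite(logits)))
    stop("non-finite transition logits; are inputs standardized?",
         call. = FALSE)
  for (i in seq_len(Z)) {
    li <- logits[, i, , drop = FALSE]
    dim(li) <- c(Tn, Z)
    mx <- row_max(li)
    e <- exp(li - mx)
    A[, i, ] <- e / rowSums(e)
  }
  A
}

#' Input-driven transition matrix for one history
#'
#' @param params a `stapaw_params` object.
#' @param C_hist concentration history, most recent value first (raw
#'   units; standardized internally). Shorter-than-kernel histories are
#'   zero-padded after standardization.
#' @param I_hist optional stimulus history, most recent first.
#' @return Z x Z stochastic matrix; entry (i, j) is P(next = j | current = i).
#' @export
transition_matrix <- function(params, C_hist, I_hist = NULL) {
  Z <- params$Z
  if (Z == 1) return(matrix(1, 1, 1))
  tr <- params$transition
  Cs <- apply_standardize(C_hist, params$standardize$C)
  A <- matrix(0, Z, Z)
  for (i in seq_len(Z)) {
    logit <- numeric(Z)
    for (j in seq_len(Z)) {
      if (i == j) { logit[j] <- tr$baseline[i]; next }
      v <- filter_history(Cs, tr$kernels[[i]][[j]], params$basis)
      if (!is.null(tr$opto) && !is.null(I_hist)) {
        o <- tr$opto[[i]][[j]]
        if (!is.null(o)) v <- v + filter_history(I_hist, o, params$basis)
      }
      logit[j] <- v
    }
    if (!all(is.finite(logit)))
      stop("non-finite transition logits; are inputs standardized?",
           call. = FALSE)
    e <- exp(logit - max(logit))
    A[i, ] <- e / sum(e)
  }
  A
}

# Vectorized per-step turn probability for one state's emission block.
turn_prob_series <- function(em, design) {
  eta <- drop(design$X_C %*% em$k_C) + drop(design$X_h %*% em$k_h)
  if (!is.null(em$k_O) && !is.null(design$X_O))
    eta <- eta + drop(design$X_O %*% em$k_O)
  em$m + (em$M - em$m) * stats::plogis(-eta)
}

#' Per-step probability of electing a turn
#'
#' Logistic turn decision bounded between the state's minimum and maximum
#' turn probabilities: `m + (M - m) / (1 + exp(filtered input))`.
#'
#' @param params a `stapaw_params` object.
#' @param z state index.
#' @param C_hist concentration history, most recent first (raw units).
#' @param dtheta_hist heading-change history, most recent first (radians;
#'   the kernel acts on its absolute value).
#' @param I_hist optional stimulus history.
#' @return probability in [m, M].
#' @export
turn_probability <- function(params, z, C_hist, dtheta_hist, I_hist = NULL) {
  em <- params$emissions[[z]]
  if (em$m > em$M) stop("m > M in emission parameters", call. = FALSE)
  Cs <- apply_standardize(C_hist, params$standardize$C)
  eta <- filter_history(Cs, em$k_C, params$basis) +
    filter_history(abs(dtheta_hist), em$k_h, params$basis)
  if (!is.null(em$k_O) && !is.null(I_hist))
    eta <- eta + filter_history(I_hist, em$k_O, params$basis)
  em$m + (em$M - em$m) * stats::plogis(-eta)
}

#' Heading-change density under a turn or weathervane strategy
#'
#' Turns (q = 1) follow a mixture of the circular uniform (weight `alpha`)
#' and a von Mises centered at pi (reversals); weathervaning (q = 0)
#' follows a von Mises whose mean is minus the steering-kernel-filtered
#' dCp history.
#'
#' @param params a `stapaw_params` object.
#' @param z state index.
#' @param dtheta heading change(s), radians in (-pi, pi].
#' @param q strategy indicator, 0 or 1.
#' @param dCp_hist perpendicular-concentration history, most recent first
#'   (raw units; only used when q = 0).
#' @return density value(s).
#' @export
heading_density <- function(params, z, dtheta, q, dCp_hist = numeric(0)) {
  em <- params$emissions[[z]]
  if (em$kappa_turn <= 0 || em$kappa_wv <= 0)
    stop("von Mises concentration must be positive", call. = FALSE)
  if (q == 1) {
    em$alpha / (2 * pi) + (1 - em$alpha) * dvonmises(dtheta, pi, em$kappa_turn)
  } else {
    dCps <- apply_standardize(dCp_hist, params$standardize$dCp)
    mu <- -filter_history(dCps, em$k_dCp, params$basis)
    dvonmises(dtheta, mu, em$kappa_wv)
  }
}

#' Speed density under a turn or weathervane strategy
#'
#' Gamma density with strategy-specific shape and scale; displacements at
#' or below zero are floored at `1e-4` cm.
#'
#' @param params a `stapaw_params` object.
#' @param z state index.
#' @param dr step displacement(s), cm.
#' @param q strategy indicator, 0 or 1.
#' @return density value(s).
#' @export
speed_density <- function(params, z, dr, q) {
  em <- params$emissions[[z]]
  g <- if (q == 1) em$gamma_turn else em$gamma_run
  stats::dgamma(pmax(dr, DR_FLOOR), shape = g[1], scale = g[2])
}

# Emission components for one state over a design. Returns the per-step
# turn probability p, and log densities of the two mixture branches.
emission_components <- function(params, z, design) {
  em <- params$emissions[[z]]
  p <- turn_prob_series(em, design)
  l_tr <- log(em$alpha / (2 * pi) +
                (1 - em$alpha) * dvonmises(design$dtheta, pi, em$kappa_turn)) +
    stats::dgamma(design$dr, shape = em$gamma_turn[1],
                  scale = em$gamma_turn[2], log = TRUE)
  mu <- -drop(design$X_dCp %*% em$k_dCp)
  l_wv <- dvonmises(design$dtheta, mu, em$kappa_wv, log = TRUE) +
    stats::dgamma(design$dr, shape = em$gamma_run[1],
                  scale = em$gamma_run[2], log = TRUE)
  list(p = p, l_tr = l_tr, l_wv = l_wv)
}

#' Emission log-likelihood matrix for a track
#'
#' Entry (t, z) is the log of the state-z mixture density
#' `P(q=1|z) Ptr(dtheta_t) G_turn(dr_t) + P(q=0|z) Pwv(dtheta_t) G_run(dr_t)`.
#'
#' @param params a `stapaw_params` object.
#' @param track a `stapaw_track` with sensory series attached.
#' @return T x Z matrix of finite log densities.
#' @export
emission_loglik <- function(params, track) {
  design <- stapaw_design(track, params)
  emission_loglik_design(params, design)
}

emission_loglik_design <- function(params, design) {
  Tn <- design$n
  out <- matrix(0, Tn, params$Z)
  for (z in seq_len(params$Z)) {
    cm <- emission_components(params, z, design)
    # log(p e^ltr + (1-p) e^lwv), stable via the larger branch
    a <- log(cm$p) + cm$l_tr
    b <- log1p(-cm$p) + cm$l_wv
    mx <- pmax(a, b)
    out[, z] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  if (!all(is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite emission log-likelihood at step %d, state %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  out
}

#' Posterior probability of a turn at each step
#'
#' Combines the state marginals with each state's turn/weathervane mixture
#' to give `P(q_t = 1 | data)`.
#'
#' @param params a `stapaw_params` object.
#' @param track a `stapaw_track`.
#' @param gamma T x Z state marginals from [forward_backward()].
#' @return numeric vector in [0, 1].
#' @export
posterior_turn_probability <- function(params, track, gamma) {
  design <- stapaw_design(track, params)
  out <- numeric(design$n)
  for (z in seq_len(params$Z)) {
    cm <- emission_components(params, z, design)
    a <- cm$p * exp(cm$l_tr)
    b <- (1 - cm$p) * exp(cm$l_wv)
    out <- out + gamma[, z] * a / (a + b)
  }
  pmin(pmax(out, 0), 1)
}
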