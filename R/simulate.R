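# Generative closed-loop simulation of navigation trajectories from any
# staPAW parameter set, open-loop sampling under fixed sensory input, and
# documented ground-truth fixture presets.
#
# Per-step update order: sense (C, dCp at the current pose) -> draw the
# next state from the input-driven transition -> draw the turn/weathervane
# decision -> draw dtheta and dr -> advance the pose (with a reflecting
# boundary). The sensory histories feeding kernels always end one step in
# the past, matching the fitting convention.

#' Simulate navigation trajectories from a parameter set
#'
#' @param params a `stapaw_params` object.
#' @param env a `stapaw_env` providing the concentration field.
#' @param n_tracks number of tracks.
#' @param n_steps steps per track.
#' @param seed integer seed; simulations are fully reproducible.
#' @param start_box optional `c(xmin, xmax, ymin, ymax)` region for uniform
#'   start positions; default is the central 60% of the domain.
#' @param sensor_offset lateral sensor offset for dCp, cm.
#' @return an object of class `stapaw_sim`: a `stapaw_dataset` whose
#'   tracks additionally carry the latent state series `z` and decision
#'   series `q`.
#' @export
simulate_stapaw <- function(params, env, n_tracks = 10, n_steps = 1000,
                            seed = 0, start_box = NULL,
                            sensor_offset = 0.05) {
  stopifnot(n_steps >= 2)
  tracks <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    tracks[[k]] <- with_seed(sub_seed(seed, k), {
      sim_one_track(params, env, n_steps, start_box, sensor_offset,
                    track_id = sprintf("sim%03d", k))
    })
  }
  ds <- stapaw_dataset(tracks, metadata = list(seed = seed))
  class(ds) <- c("stapaw_sim", class(ds))
  ds
}

default_start_box <- function(env) {
  if (inherits(env, "stapaw_env_gaussian")) {
    r <- env$radius * 0.6
    c(env$center[1] - r, env$center[1] + r,
      env$center[2] - r, env$center[2] + r)
  } else {
    b <- env$bounds
    mx <- mean(b[1:2]); my <- mean(b[3:4])
    wx <- diff(b[1:2]) * 0.3; wy <- diff(b[3:4]) * 0.3
    c(mx - wx, mx + wx, my - wy, my + wy)
  }
}

sim_one_track <- function(params, env, n_steps, start_box, sensor_offset,
                          track_id) {
  L <- params$basis$n_lag
  Z <- params$Z
  box <- start_box %||% default_start_box(env)
  pos <- c(stats::runif(1, box[1], box[2]), stats::runif(1, box[3], box[4]))
  pos <- reflect_position(env, pos)
  heading <- stats::runif(1, -pi, pi)
  z <- sample.int(Z, 1, prob = params$init_dist)

  # recent-first standardized history buffers (zero = dataset mean)
  hC <- rep(0, L); hdCp <- rep(0, L); hAbs <- rep(0, L); hI <- rep(0, L)
  # realized lag weights, precomputed
  W <- realized_lag_weights(params)
  opto <- has_opto(params)

  n <- n_steps
  out <- list(t = numeric(n), x = numeric(n), y = numeric(n),
              heading = numeric(n), dtheta = numeric(n), dr = numeric(n),
              C = numeric(n), dCp = numeric(n), z = integer(n),
              q = integer(n))
  sense <- function(pos, heading) {
    u_perp <- c(cos(heading + pi / 2), sin(heading + pi / 2))
    pl <- reflect_position(env, pos + sensor_offset * u_perp)
    pr <- reflect_position(env, pos - sensor_offset * u_perp)
    c(concentration(env, pos),
      concentration(env, pl) - concentration(env, pr))
  }
  s <- sense(pos, heading)
  push <- function(buf, val) c(val, buf[-length(buf)])
  hC <- push(hC, apply_standardize(s[1], params$standardize$C))
  hdCp <- push(hdCp, apply_standardize(s[2], params$standardize$dCp))

  for (t in seq_len(n)) {
    # state transition driven by concentration (and stimulus) history
    if (Z > 1) {
      logit <- numeric(Z)
      for (j in seq_len(Z)) {
        if (j == z) { logit[j] <- params$transition$baseline[z]; next }
        v <- sum(W$trans[[z]][[j]] * hC)
        if (opto && !is.null(W$trans_o[[z]][[j]]))
          v <- v + sum(W$trans_o[[z]][[j]] * hI)
        logit[j] <- v
      }
      pz <- exp(logit - max(logit)); pz <- pz / sum(pz)
      z <- sample.int(Z, 1, prob = pz)
    }
    em <- params$emissions[[z]]
    eta <- sum(W$k_C[[z]] * hC) + sum(W$k_h[[z]] * hAbs)
    if (opto && !is.null(W$k_O[[z]])) eta <- eta + sum(W$k_O[[z]] * hI)
    p_turn <- em$m + (em$M - em$m) * stats::plogis(-eta)
    q <- as.integer(stats::runif(1) < p_turn)
    if (q == 1) {
      dth <- if (stats::runif(1) < em$alpha) stats::runif(1, -pi, pi)
             else rvonmises(1, pi, em$kappa_turn)
      dr <- stats::rgamma(1, shape = em$gamma_turn[1],
                          scale = em$gamma_turn[2])
    } else {
      mu <- -sum(W$k_dCp[[z]] * hdCp)
      dth <- rvonmises(1, mu, em$kappa_wv)
      dr <- stats::rgamma(1, shape = em$gamma_run[1],
                          scale = em$gamma_run[2])
    }
    heading <- wrap_angle(heading + dth)
    pos_new <- pos + dr * c(cos(heading), sin(heading))
    pos_new <- reflect_position(env, pos_new)
    pos <- pos_new
    s <- sense(pos, heading)
    out$t[t] <- t * params$dt
    out$x[t] <- pos[1]; out$y[t] <- pos[2]
    out$heading[t] <- heading
    out$dtheta[t] <- dth; out$dr[t] <- dr
    out$C[t] <- s[1]; out$dCp[t] <- s[2]
    out$z[t] <- z; out$q[t] <- q
    hC <- push(hC, apply_standardize(s[1], params$standardize$C))
    hdCp <- push(hdCp, apply_standardize(s[2], params$standardize$dCp))
    hAbs <- push(hAbs, abs(dth))
    hI <- push(hI, 0)
  }
  tr <- new_track(track_id = track_id, dt = params$dt, t = out$t,
                  x = out$x, y = out$y, heading = out$heading,
                  dtheta = out$dtheta, dr = out$dr,
                  C = out$C, dCp = out$dCp)
  tr$z <- out$z
  tr$q <- out$q
  tr
}

realized_lag_weights <- function(params) {
  basis <- params$basis
  Z <- params$Z
  rw <- function(coef) if (is.null(coef)) NULL else realized_weights(coef, basis)
  trans <- trans_o <- NULL
  if (Z > 1) {
    trans <- lapply(seq_len(Z), function(i)
      lapply(seq_len(Z), function(j)
        if (i == j) NULL else rw(params$transition$kernels[[i]][[j]])))
    trans_o <- lapply(seq_len(Z), function(i)
      lapply(seq_len(Z), function(j)
        if (i == j || is.null(params$transition$opto)) NULL
        else rw(params$transition$opto[[i]][[j]])))
  }
  list(trans = trans, trans_o = trans_o,
       k_C = lapply(params$emissions, function(e) rw(e$k_C)),
       k_h = lapply(params$emissions, function(e) rw(e$k_h)),
       k_O = lapply(params$emissions, function(e) rw(e$k_O)),
       k_dCp = lapply(params$emissions, function(e) rw(e$k_dCp)))
}

#' Open-loop sampling under fixed sensory input
#'
#' Draws latent states and kinematics under externally supplied sensory
#' series (no feedback through position); used for stimulus-locked
#' analyses such as optogenetic pulse responses.
#'
#' @param params a `stapaw_params` object.
#' @param C concentration series (raw units).
#' @param dCp perpendicular concentration series; default zero.
#' @param I optional stimulus series (same length).
#' @param seed integer seed.
#' @return list with `z`, `q`, `dtheta`, `dr` series.
#' @export
simulate_open_loop <- function(params, C, dCp = NULL, I = NULL, seed = 0) {
  Tn <- length(C)
  if (is.null(dCp)) dCp <- rep(0, Tn)
  if (length(dCp) != Tn || (!is.null(I) && length(I) != Tn))
    stop("sensory series length mismatch", call. = FALSE)
  with_seed(sub_seed(seed, 31L), {
    L <- params$basis$n_lag
    Z <- params$Z
    W <- realized_lag_weights(params)
    opto <- has_opto(params) && !is.null(I)
    hC <- rep(0, L); hdCp <- rep(0, L); hAbs <- rep(0, L); hI <- rep(0, L)
    push <- function(buf, val) c(val, buf[-length(buf)])
    z <- sample.int(Z, 1, prob = params$init_dist)
    out_z <- integer(Tn); out_q <- integer(Tn)
    out_dth <- numeric(Tn); out_dr <- numeric(Tn)
    for (t in seq_len(Tn)) {
      if (Z > 1) {
        logit <- numeric(Z)
        for (j in seq_len(Z)) {
          if (j == z) { logit[j] <- params$transition$baseline[z]; next }
          v <- sum(W$trans[[z]][[j]] * hC)
          if (opto && !is.null(W$trans_o[[z]][[j]]))
            v <- v + sum(W$trans_o[[z]][[j]] * hI)
          logit[j] <- v
        }
        pz <- exp(logit - max(logit)); pz <- pz / sum(pz)
        z <- sample.int(Z, 1, prob = pz)
      }
      em <- params$emissions[[z]]
      eta <- sum(W$k_C[[z]] * hC) + sum(W$k_h[[z]] * hAbs)
      if (opto && !is.null(W$k_O[[z]])) eta <- eta + sum(W$k_O[[z]] * hI)
      p_turn <- em$m + (em$M - em$m) * stats::plogis(-eta)
      q <- as.integer(stats::runif(1) < p_turn)
      if (q == 1) {
        dth <- if (stats::runif(1) < em$alpha) stats::runif(1, -pi, pi)
               else rvonmises(1, pi, em$kappa_turn)
        dr <- stats::rgamma(1, shape = em$gamma_turn[1],
                            scale = em$gamma_turn[2])
      } else {
        mu <- -sum(W$k_dCp[[z]] * hdCp)
        dth <- rvonmises(1, mu, em$kappa_wv)
        dr <- stats::rgamma(1, shape = em$gamma_run[1],
                            scale = em$gamma_run[2])
      }
      out_z[t] <- z; out_q[t] <- q; out_dth[t] <- dth; out_dr[t] <- dr
      hC <- push(hC, apply_standardize(C[t], params$standardize$C))
      hdCp <- push(hdCp, apply_standardize(dCp[t], params$standardize$dCp))
      hAbs <- push(hAbs, abs(dth))
      hI <- push(hI, if (is.null(I)) 0 else I[t])
    }
    list(z = out_z, q = out_q, dtheta = out_dth, dr = out_dr)
  })
}

#' Ground-truth fixture parameter presets
#'
#' Documented two-state (and one-state) parameter sets used throughout the
#' test suite and examples. `"paperlike-2state"` has a steer-enriched
#' state S (state 1: rare turns, faster runs, active steering kernel) and
#' a turn-enriched state T (state 2: frequent turns, slower, turn kernel
#' active), with mirror-image derivative-shaped transition kernels so that
#' falling concentration drives S -> T and rising concentration drives
#' T -> S. Sensory-free dwell times are seconds-scale (about 8 s in S and
#' 5 s in T at the default step of 5/14 s). `"hmm-2state"` is identical
#' but with the transition kernels set exactly to zero;
#' `"dpaw-1state"` is the single-state reduction; `"opto-2state"` adds
#' stimulus kernels that drive S -> T while the light is on.
#'
#' @param preset one of `"paperlike-2state"`, `"hmm-2state"`,
#'   `"dpaw-1state"`, `"opto-2state"`.
#' @param flip_transition_sign negate both transition kernels (goal
#'   reversal; down-gradient exits become preferred).
#' @return a `stapaw_params` object.
#' @export
fixture_params <- function(preset = c("paperlike-2state", "hmm-2state",
                                      "dpaw-1state", "opto-2state"),
                           flip_transition_sign = FALSE) {
  preset <- match.arg(preset)
  basis <- stapaw_basis(4, 14)
  dt <- 5 / 14
  nb <- basis$n_basis
  opto <- preset == "opto-2state"
  # standardization constants matching closed-loop runs in the default
  # 0-50 mM linear arena (mean mid-arena, sd from track spread)
  std <- list(C = c(mean = 25, sd = 10), dCp = c(mean = 0, sd = 0.25))

  # zero-sum derivative-shaped kernel in the basis span: positive recent
  # lobe, negative older lobe, insensitive to the standing input level
  deriv <- local({
    coef <- c(1, -0.5, -0.5, 0)
    s <- colSums(basis$Phi)
    coef <- coef - s * sum(s * coef) / sum(s * s)
    coef / max(abs(realized_weights(coef, stapaw_basis(4, 14))))
  })
  bump <- c(1, 0, 0, 0)  # recent-lags-only bump

  # steer-enriched state: few turns, faster runs, steering kernel on,
  # strong derivative turn kernel (biased-random-walk component)
  em_S <- emission_params(
    M = 0.25, m = 0.05, alpha = 0.30, kappa_turn = 3.5, kappa_wv = 12,
    k_C = 10 * deriv, k_h = c(0.8, -0.5, 0, 0),
    k_dCp = -0.05 * bump,
    gamma_turn = c(2.5, 0.0010), gamma_run = c(6, 0.0011),
    k_O = if (opto) rep(0, nb) else NULL)
  # turn-enriched state: frequent reversals, slower; steering is
  # suppressed while turning (k_dCp = 0)
  em_T <- emission_params(
    M = 0.70, m = 0.12, alpha = 0.30, kappa_turn = 3.0, kappa_wv = 9,
    k_C = 8 * deriv, k_h = c(0.9, -0.4, 0, 0),
    k_dCp = 0 * bump,
    gamma_turn = c(2.5, 0.0008), gamma_run = c(6, 0.0008),
    k_O = if (opto) rep(0, nb) else NULL)

  if (preset == "dpaw-1state") {
    em <- em_S
    em$M <- 0.25; em$kappa_wv <- 6
    em$k_O <- NULL
    return(stapaw_params(Z = 1, dt = dt, basis = basis,
                         emissions = list(em),
                         transition = transition_params(1, baseline = 0),
                         init_dist = 1, standardize = std))
  }

  # mirror-shaped derivative transition kernels (different scales):
  # K(T->S) fires on rising concentration, K(S->T) on falling
  k_TS <- 60 * deriv
  k_ST <- -60 * deriv
  if (preset == "hmm-2state") {
    k_TS <- rep(0, nb); k_ST <- rep(0, nb)
  }
  if (flip_transition_sign) {
    k_TS <- -k_TS; k_ST <- -k_ST
  }
  kernels <- list(list(NULL, k_ST), list(k_TS, NULL))
  # baselines: sensory-free dwell ~ 8.1 s (S) and ~ 4.6 s (T)
  b_S <- stats::qlogis(1 - dt / 8.1)
  b_T <- stats::qlogis(1 - dt / 4.6)
  opto_k <- NULL
  if (opto) {
    # light drives S -> T (and mildly suppresses T -> S)
    opto_k <- list(list(NULL, c(0.35, 0.12, 0, 0)),
                   list(c(-0.18, -0.06, 0, 0), NULL))
  }
  trans <- transition_params(2, baseline = c(b_S, b_T),
                             kernels = kernels, opto = opto_k)
  stapaw_params(Z = 2, dt = dt, basis = basis,
                emissions = list(em_S, em_T), transition = trans,
                init_dist = c(0.64, 0.36), standardize = std)
}
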