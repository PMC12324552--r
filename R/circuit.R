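# Minimal mutual-inhibition rate circuit: two noisy rate units (S and T)
# receive oppositely signed filtered sensory input; the more active unit
# dictates the behavioral strategy, and mutual inhibition makes the winner
# persist on a seconds timescale.

#' Circuit parameters
#'
#' Two-unit rate network `tau dx_i/dt = -x_i + sum_j J_ij phi(x_j) +
#' B_i I(t) + xi_i`, with a rectified-linear `phi`, white noise scaled by
#' `sqrt(dt)`, and a fast/slow sensory filter producing the input
#' `I = F - S` from the experienced concentration.
#'
#' @param tau membrane time constant, s.
#' @param J 2 x 2 coupling matrix (zero diagonal; negative off-diagonal
#'   entries give mutual inhibition). A scalar is interpreted as the
#'   common off-diagonal coupling.
#' @param B length-2 input weights for the (S, T) units; the default
#'   `c(1, -1)` excites the steer unit when concentration rises and the
#'   turn unit when it falls.
#' @param noise white-noise amplitude.
#' @param alpha,beta,gamma fast/slow sensory-filter coefficients
#'   (`dF/dt = alpha C - beta F`, `dS/dt = gamma (F - S)`).
#' @param dt Euler integration step, s (default 0.1).
#' @return an object of class `stapaw_circuit`.
#' @export
circuit_params <- function(tau = 1, J = -4, B = c(1, -1), noise = 0.9,
                           alpha = 1, beta = 0.5, gamma = 0.1, dt = 0.1) {
  if (length(J) == 1) J <- matrix(c(0, J, J, 0), 2, 2)
  stopifnot(tau > 0, dt > 0, nrow(J) == 2, ncol(J) == 2,
            all(diag(J) == 0), length(B) == 2, noise >= 0,
            alpha > 0, beta > 0, gamma > 0)
  if (dt >= 2 * tau || dt * beta >= 2 || dt * gamma >= 2)
    stop("integration step too large for the given rates", call. = FALSE)
  structure(list(tau = tau, J = J, B = as.numeric(B), noise = noise,
                 alpha = alpha, beta = beta, gamma = gamma, dt = dt,
                 units = c("S", "T")),
            class = "stapaw_circuit")
}

#' Fast/slow sensory filtering of a concentration series
#'
#' Euler integration of `dF/dt = alpha C - beta F` and
#' `dS/dt = gamma (F - S)`; the circuit input is `I = F - S`, a transient
#' signal that responds to concentration changes and adapts back to zero.
#'
#' @param C concentration series.
#' @param params a [circuit_params()] (uses alpha, beta, gamma, dt).
#' @param F0,S0 initial filter states; defaults start at the steady state
#'   for `C[1]`.
#' @return list with `F`, `S` and `I = F - S` series.
#' @export
sensory_filter <- function(C, params, F0 = NULL, S0 = NULL) {
  stopifnot(all(is.finite(C)))
  n <- length(C)
  dt <- params$dt
  Fv <- numeric(n); Sv <- numeric(n)
  f <- F0 %||% (params$alpha * C[1] / params$beta)
  s <- S0 %||% f
  for (t in seq_len(n)) {
    f <- f + dt * (params$alpha * C[t] - params$beta * f)
    s <- s + dt * params$gamma * (f - s)
    Fv[t] <- f; Sv[t] <- s
  }
  list(F = Fv, S = Sv, I = Fv - Sv)
}

#' Integrate the two-unit circuit under a given input series
#'
#' Euler integration with seeded white noise; the winner at each step is
#' the unit with the larger activity, with ties broken toward the current
#' winner (sticky argmax).
#'
#' @param params a [circuit_params()].
#' @param I input series (from [sensory_filter()]).
#' @param seed noise seed.
#' @param x0 initial activities (default 0, 0).
#' @return list with `x` (n x 2 activity matrix) and `winner` (1 = S,
#'   2 = T).
#' @export
integrate_circuit <- function(params, I, seed = 0, x0 = c(0, 0)) {
  n <- length(I)
  with_seed(sub_seed(seed, 13L), {
    x <- matrix(0, n, 2)
    winner <- integer(n)
    xi <- x0
    w <- if (x0[1] >= x0[2]) 1L else 2L
    dt <- params$dt
    sq <- params$noise * sqrt(dt)
    relu <- function(v) pmax(v, 0)
    for (t in seq_len(n)) {
      drive <- params$J %*% relu(xi) + params$B * I[t]
      xi <- xi + (dt / params$tau) * (-xi + drive) + sq * stats::rnorm(2)
      if (!all(is.finite(xi)))
        stop("non-finite circuit activity at step ", t, call. = FALSE)
      x[t, ] <- xi
      if (xi[1] > xi[2]) w <- 1L else if (xi[2] > xi[1]) w <- 2L
      winner[t] <- w
    }
    list(x = x, winner = winner)
  })
}

#' Closed-loop navigation under circuit control
#'
#' At each Euler step the agent senses the local concentration, updates
#' the sensory filters and the two-unit circuit, and behaves according to
#' the winning unit: the S unit steers (weathervane kinematics), the T
#' unit produces broad reversal-like turns at lower speed.
#'
#' @param params a [circuit_params()].
#' @param env environment (Gaussian plume by default usage).
#' @param n_tracks number of trajectories (default 200).
#' @param n_steps steps per trajectory at `params$dt`.
#' @param motif with the mutual-inhibition coupling (`TRUE`) or the
#'   uncoupled `J = 0` control (`FALSE`).
#' @param seed master seed.
#' @param speed length-2 step displacements (cm per step) for S and T
#'   winners.
#' @param kin heading-change parameters, as in [rl_config()] kinematics.
#' @param start_radius start distance from the plume center, cm.
#' @param ci_radius chemotaxis success radius (default 0.5 sigma).
#' @return list with `ci`, `dwell_s` (per-state dwell-time samples, s),
#'   `final_dist`, `winner_frac_T`.
#' @export
run_navigation <- function(params, env, n_tracks = 200, n_steps = 600,
                           motif = TRUE, seed = 0, speed = c(0.01, 0.004),
                           kin = NULL, start_radius = 3, ci_radius = NULL) {
  stopifnot(inherits(env, "stapaw_env_gaussian"))
  if (!motif) params$J <- matrix(0, 2, 2)
  if (is.null(kin))
    kin <- list(kappa_wv = 8, steer_gain = 1.5, alpha = 0.3, kappa_turn = 1.2)
  ci_radius <- ci_radius %||% (env$sigma * 0.5)
  dt <- params$dt
  finals <- numeric(n_tracks)
  dwell <- list(S = c(), T = c())
  fracT <- numeric(n_tracks)
  for (k in seq_len(n_tracks)) {
    res <- with_seed(sub_seed(seed, 400L + k), {
      ang <- stats::runif(1, -pi, pi)
      pos <- reflect_position(env, env$center +
                                start_radius * c(cos(ang), sin(ang)))
      heading <- stats::runif(1, -pi, pi)
      f <- params$alpha * concentration(env, pos) / params$beta
      s <- f
      xi <- c(0, 0)
      w <- 1L
      winners <- integer(n_steps)
      sq <- params$noise * sqrt(dt)
      for (t in seq_len(n_steps)) {
        Cn <- concentration(env, pos)
        f <- f + dt * (params$alpha * Cn - params$beta * f)
        s <- s + dt * params$gamma * (f - s)
        I <- f - s
        drive <- params$J %*% pmax(xi, 0) + params$B * I
        xi <- xi + (dt / params$tau) * (-xi + drive) + sq * stats::rnorm(2)
        if (xi[1] > xi[2]) w <- 1L else if (xi[2] > xi[1]) w <- 2L
        winners[t] <- w
        if (w == 2L) {
          dth <- if (stats::runif(1) < kin$alpha) stats::runif(1, -pi, pi)
                 else rvonmises(1, pi, kin$kappa_turn)
        } else {
          off <- 0.05
          u_perp <- c(cos(heading + pi / 2), sin(heading + pi / 2))
          pl <- reflect_position(env, pos + off * u_perp)
          pr <- reflect_position(env, pos - off * u_perp)
          dCp <- concentration(env, pl) - concentration(env, pr)
          gmag <- sqrt(sum(env_gradient(env, pos)^2))
          dCp_n <- if (gmag > 1e-12) dCp / (2 * off * gmag) else 0
          dth <- rvonmises(1, kin$steer_gain * dCp_n * 0.1, kin$kappa_wv)
        }
        heading <- wrap_angle(heading + dth)
        pos <- reflect_position(env,
          pos + speed[w] * c(cos(heading), sin(heading)))
      }
      list(final = pos, winners = winners)
    })
    finals[k] <- sqrt(sum((res$final - env$center)^2))
    r <- rle(res$winners)
    dwell$S <- c(dwell$S, r$lengths[r$values == 1L] * dt)
    dwell$T <- c(dwell$T, r$lengths[r$values == 2L] * dt)
    fracT[k] <- mean(res$winners == 2L)
  }
  list(ci = mean(finals <= ci_radius), dwell_s = dwell,
       final_dist = finals, winner_frac_T = mean(fracT))
}
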