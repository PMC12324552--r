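# Data-constrained reinforcement-learning navigation agent.
#
# A two-action POMDP: at each step the agent senses only the one-step
# concentration difference dC and chooses between a weathervane-like
# action (a = 0: small heading changes with gradient steering) and a
# turn-like action (a = 1: broad/reversal heading changes), with
# kinematics fixed to the state-conditioned heading-change statistics of
# the fixture parameter presets and constant speed. Only the sensory
# dependence of action selection is learned, by REINFORCE with an Adam
# update.

#' Logistic switching policy
#'
#' @param K scalar weight on the one-step concentration difference.
#' @param b baseline logit.
#' @return an object of class `stapaw_policy`.
#' @export
rl_policy <- function(K = 0, b = 0) {
  stopifnot(is.finite(K), is.finite(b))
  structure(list(K = K, b = b), class = "stapaw_policy")
}

#' Probability that the policy selects the turn action
#'
#' `P(a = 1 | dC) = 1 / (1 + exp(K dC + b))`.
#'
#' @param policy a [rl_policy()].
#' @param dC one-step concentration difference(s).
#' @return probabilities in (0, 1).
#' @export
policy_prob <- function(policy, dC) {
  stopifnot(all(is.finite(dC)))
  1 / (1 + exp(policy$K * dC + policy$b))
}

#' RL configuration
#'
#' @param env Gaussian training environment.
#' @param epochs training epochs (one episode each; default 1000).
#' @param episode_steps steps per episode.
#' @param speed constant step displacement, cm.
#' @param lambda switching-penalty weight.
#' @param phi_tau exponential action-filter time constant, steps.
#' @param discount temporal discount factor in [0, 1).
#' @param lr Adam learning rate.
#' @param batch episodes per epoch; gradients are averaged over the
#'   batch, which tames the variance of the policy-gradient estimate.
#' @param ci_radius chemotaxis-index success radius; when NULL (the
#'   default) it resolves to half the sigma of whichever environment an
#'   evaluation runs in.
#' @param kinematics list with the action-conditioned heading-change
#'   parameters (`kappa_wv`, `steer_gain`, `alpha`, `kappa_turn`); the
#'   defaults take the steer- and turn-state statistics of the
#'   `paperlike-2state` preset.
#' @param start_radius mean start distance from the source, cm.
#' @param seed master seed.
#' @return an object of class `stapaw_rl_config`.
#' @export
rl_config <- function(env = env_gaussian(amplitude = 50), epochs = 1000,
                      episode_steps = 400, speed = 0.01,
                      lambda = 0.02, phi_tau = 5, discount = 0.98,
                      lr = 0.05, batch = 5, ci_radius = NULL,
                      kinematics = NULL, start_radius = 3, seed = 0) {
  stopifnot(inherits(env, "stapaw_env_gaussian"), epochs >= 1,
            discount >= 0, discount < 1, lambda >= 0, phi_tau > 0, lr >= 0)
  if (is.null(kinematics)) {
    fx <- fixture_params("paperlike-2state")
    kinematics <- list(
      kappa_wv = fx$emissions[[1]]$kappa_wv,
      steer_gain = 0.5,  # weak steering: heading corrects slowly in a = 0
      alpha = fx$emissions[[2]]$alpha,
      kappa_turn = fx$emissions[[2]]$kappa_turn)
  }
  structure(list(env = env, epochs = epochs, episode_steps = episode_steps,
                 speed = speed, lambda = lambda, phi_tau = phi_tau,
                 discount = discount, lr = lr, batch = as.integer(batch),
                 ci_radius = ci_radius,
                 kinematics = kinematics, start_radius = start_radius,
                 seed = seed),
            class = "stapaw_rl_config")
}

#' Switching-penalized navigation reward
#'
#' The reward is `-d(s, s*) - lambda * phi`, where `phi` is an exponential filter of
#' the discrete actions (`phi <- exp(-1/tau) phi + a`).
#'
#' @param position length-2 agent position.
#' @param source length-2 source position.
#' @param phi current value of the action filter.
#' @param lambda penalty weight.
#' @return scalar reward.
#' @export
rl_reward <- function(position, source, phi, lambda) {
  -sqrt(sum((position - source)^2)) - lambda * phi
}

#' One kinematic step of the RL agent
#'
#' Draws the heading change for the chosen action (weathervane-like with
#' gradient steering for a = 0, broad turn mixture for a = 1), advances at
#' constant speed with a reflecting boundary, and returns the new pose
#' with the concentration difference observed over the move.
#'
#' @param env environment.
#' @param position,heading current pose.
#' @param action 0 or 1.
#' @param cfg a [rl_config()].
#' @return list with `position`, `heading`, `dC`, `dtheta`.
#' @export
rl_step <- function(env, position, heading, action, cfg) {
  kin <- cfg$kinematics
  C0 <- concentration(env, position)
  if (action == 1) {
    dth <- if (stats::runif(1) < kin$alpha) stats::runif(1, -pi, pi)
           else rvonmises(1, pi, kin$kappa_turn)
  } else {
    off <- 0.05
    u_perp <- c(cos(heading + pi / 2), sin(heading + pi / 2))
    pl <- reflect_position(env, position + off * u_perp)
    pr <- reflect_position(env, position - off * u_perp)
    dCp <- concentration(env, pl) - concentration(env, pr)
    # normalize the steering signal by its local scale
    gmag <- sqrt(sum(env_gradient(env, position)^2))
    dCp_n <- if (gmag > 1e-12) dCp / (2 * off * gmag) else 0
    dth <- rvonmises(1, kin$steer_gain * dCp_n * 0.1, kin$kappa_wv)
  }
  heading <- wrap_angle(heading + dth)
  position <- reflect_position(env,
    position + cfg$speed * c(cos(heading), sin(heading)))
  list(position = position, heading = heading,
       dC = concentration(env, position) - C0, dtheta = dth)
}

run_episode <- function(policy, cfg, mode = "policy",
                        actions_override = NULL, switch_prob = NULL) {
  env <- cfg$env
  kin <- cfg$kinematics
  n <- cfg$episode_steps
  # inlined Gaussian field queries keep the episode loop fast
  cx <- env$center[1]; cy <- env$center[2]
  s2 <- env$sigma^2; amp <- env$amplitude; rad <- env$radius
  conc <- function(px, py) {
    amp * exp(-((px - cx)^2 + (py - cy)^2) / (2 * s2))
  }
  ang <- stats::runif(1, -pi, pi)
  px <- cx + cfg$start_radius * cos(ang)
  py <- cy + cfg$start_radius * sin(ang)
  heading <- stats::runif(1, -pi, pi)
  decay <- exp(-1 / cfg$phi_tau)
  phi <- 0
  dC <- 0
  a_prev <- 0L
  pK <- policy$K; pb <- policy$b
  actions <- integer(n); rewards <- numeric(n); dCs <- numeric(n)
  dths <- numeric(n)
  C0 <- conc(px, py)
  off <- 0.05
  for (t in seq_len(n)) {
    a <- switch(mode,
      policy = as.integer(stats::runif(1) < 1 / (1 + exp(pK * dC + pb))),
      fixed0 = 0L,
      fixed1 = 1L,
      replay = actions_override[t],
      markov = if (stats::runif(1) < switch_prob) 1L - a_prev else a_prev)
    if (a == 1L) {
      dth <- if (stats::runif(1) < kin$alpha) stats::runif(1, -pi, pi)
             else rvonmises(1, pi, kin$kappa_turn)
    } else {
      ux <- cos(heading + pi / 2); uy <- sin(heading + pi / 2)
      dCp <- conc(px + off * ux, py + off * uy) -
        conc(px - off * ux, py - off * uy)
      gmag <- sqrt((px - cx)^2 + (py - cy)^2) / s2 * C0
      dCp_n <- if (gmag > 1e-12) dCp / (2 * off * gmag) else 0
      dth <- rvonmises(1, kin$steer_gain * dCp_n * 0.1, kin$kappa_wv)
    }
    heading <- wrap_angle(heading + dth)
    px2 <- px + cfg$speed * cos(heading)
    py2 <- py + cfg$speed * sin(heading)
    # radial reflection at the domain edge
    dd <- sqrt((px2 - cx)^2 + (py2 - cy)^2)
    if (dd > rad) {
      f <- (2 * rad - dd) / dd
      px2 <- cx + (px2 - cx) * f
      py2 <- cy + (py2 - cy) * f
    }
    px <- px2; py <- py2
    C1 <- conc(px, py)
    phi <- decay * phi + a
    rewards[t] <- -sqrt((px - cx)^2 + (py - cy)^2) - cfg$lambda * phi
    actions[t] <- a; dCs[t] <- dC; dths[t] <- dth
    dC <- C1 - C0
    C0 <- C1
    a_prev <- a
  }
  list(actions = actions, rewards = rewards, dC_obs = dCs, dtheta = dths,
       final = c(px, py),
       final_dist = sqrt((px - cx)^2 + (py - cy)^2))
}

#' Train the switching policy by policy gradient
#'
#' REINFORCE on the discounted return with a mean-return baseline and Adam
#' learning-rate adaptation; one episode per epoch. Returns the trained
#' policy and learning curves (per-epoch total reward, its 50-epoch
#' running average, and the chemotaxis index of each 50-epoch block).
#'
#' @param cfg a [rl_config()].
#' @param policy optional starting policy (default K = 0, b = 0).
#' @return an object of class `stapaw_rl_fit`: list with `policy`,
#'   `reward_curve`, `reward_running`, `ci_curve`, `cfg`.
#' @export
rl_train <- function(cfg, policy = rl_policy()) {
  mK <- 0; vK <- 0; mb <- 0; vb <- 0  # Adam moments
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  rewards <- numeric(cfg$epochs)
  finals <- numeric(cfg$epochs)
  gam <- cfg$discount
  for (ep in seq_len(cfg$epochs)) {
    gK <- 0; gb <- 0; ep_reward <- 0; ep_final <- 0
    for (bi in seq_len(cfg$batch)) {
      epi <- with_seed(sub_seed(cfg$seed, 1000L + ep * 31L + bi),
                       run_episode(policy, cfg, mode = "policy"))
      n <- length(epi$rewards)
      G <- rev(cumsum(rev(epi$rewards * gam^(seq_len(n) - 1)))) /
        gam^(seq_len(n) - 1)
      adv <- G - mean(G)
      p1 <- policy_prob(policy, epi$dC_obs)
      # d log pi / d u with u = K dC + b: -(1 - p1) for a = 1, p1 for a = 0
      dldu <- ifelse(epi$actions == 1, -(1 - p1), p1)
      gK <- gK + sum(adv * dldu * epi$dC_obs) / cfg$batch
      gb <- gb + sum(adv * dldu) / cfg$batch
      ep_reward <- ep_reward + sum(epi$rewards) / cfg$batch
      ep_final <- ep_final + epi$final_dist / cfg$batch
    }
    if (!is.finite(gK) || !is.finite(gb))
      stop("non-finite policy gradient at epoch ", ep, call. = FALSE)
    mK <- beta1 * mK + (1 - beta1) * gK; vK <- beta2 * vK + (1 - beta2) * gK^2
    mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
    t_ <- ep
    policy$K <- policy$K + cfg$lr * (mK / (1 - beta1^t_)) /
      (sqrt(vK / (1 - beta2^t_)) + eps)
    policy$b <- policy$b + cfg$lr * (mb / (1 - beta1^t_)) /
      (sqrt(vb / (1 - beta2^t_)) + eps)
    rewards[ep] <- ep_reward
    finals[ep] <- ep_final
  }
  block <- ceiling(seq_along(rewards) / 50)
  structure(list(
    policy = policy,
    reward_curve = rewards,
    reward_running = {
      w <- min(50L, length(rewards))
      as.numeric(stats::filter(rewards, rep(1 / w, w), sides = 1))
    },
    ci_curve = tapply(finals <= (cfg$ci_radius %||%
                                    (0.5 * cfg$env$sigma)), block, mean),
    cfg = cfg), class = "stapaw_rl_fit")
}

#' @export
print.stapaw_rl_fit <- function(x, ...) {
  cat(sprintf("<RL fit: K = %.3f, b = %.3f, final 50-epoch CI = %.2f>\n",
              x$policy$K, x$policy$b,
              utils::tail(x$ci_curve, 1)))
  invisible(x)
}

#' Evaluate a policy or control agent
#'
#' Runs seeded evaluation episodes and reports the chemotaxis index and
#' final distances. Controls: `"shuffled"` replays the trained agent's
#' action sequences permuted within episode (the stateless control with
#' identical action statistics); `"fixed0"`/`"fixed1"` always weathervane
#' or always turn; `"markov"` switches actions with a sensory-independent
#' probability matched to the trained agent's switch rate.
#'
#' @param policy a `stapaw_policy` (or a `stapaw_rl_fit`).
#' @param cfg a [rl_config()]; evaluation can use a different environment
#'   than training (e.g. a widened plume).
#' @param control `"trained"`, `"shuffled"`, `"fixed0"`, `"fixed1"`, or
#'   `"markov"`.
#' @param n_episodes number of evaluation episodes (default 200).
#' @param seed evaluation seed.
#' @return list with `ci`, `final_dist`, `actions` (pooled action
#'   fraction), `dtheta` (pooled heading changes).
#' @export
rl_evaluate <- function(policy, cfg,
                        control = c("trained", "shuffled", "fixed0",
                                    "fixed1", "markov"),
                        n_episodes = 200, seed = 1) {
  control <- match.arg(control)
  if (inherits(policy, "stapaw_rl_fit")) policy <- policy$policy
  finals <- numeric(n_episodes)
  act_frac <- numeric(n_episodes)
  dths <- vector("list", n_episodes)
  switch_prob <- NULL
  if (control == "markov") {
    # match the trained agent's sensory-free switch rate
    probe <- lapply(seq_len(20), function(k)
      with_seed(sub_seed(seed, 5000L + k),
                run_episode(policy, cfg, mode = "policy")))
    acts <- unlist(lapply(probe, `[[`, "actions"))
    switch_prob <- mean(acts[-1] != acts[-length(acts)])
  }
  for (k in seq_len(n_episodes)) {
    epi <- with_seed(sub_seed(seed, 2000L + k), {
      if (control %in% c("trained", "markov", "fixed0", "fixed1")) {
        run_episode(policy, cfg,
                    mode = switch(control, trained = "policy",
                                  markov = "markov", fixed0 = "fixed0",
                                  fixed1 = "fixed1"),
                    switch_prob = switch_prob)
      } else {
        base <- run_episode(policy, cfg, mode = "policy")
        perm <- sample(length(base$actions))
        run_episode(policy, cfg, mode = "replay",
                    actions_override = base$actions[perm])
      }
    })
    finals[k] <- epi$final_dist
    act_frac[k] <- mean(epi$actions)
    dths[[k]] <- epi$dtheta
  }
  radius <- cfg$ci_radius %||% (0.5 * cfg$env$sigma)
  list(ci = mean(finals <= radius), final_dist = finals,
       action_fraction = mean(act_frac), dtheta = unlist(dths),
       control = control)
}
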