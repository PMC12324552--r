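# Shared helpers: small synthetic trajectories and parameter sets built in
# code at test time.

# a raw trajectory moving at constant velocity (vx, vy) cm/s at 14 Hz
make_straight_raw <- function(n = 100, vx = 0.02, vy = 0, frame_rate = 14,
                              x0 = 1, y0 = 1, id = "w1") {
  t <- (seq_len(n) - 1) / frame_rate
  raw_trajectory(id, t, x0 + vx * t, y0 + vy * t, frame_rate = frame_rate)
}

# minimal two-state parameter set with controllable kernels
make_tiny_params <- function(Z = 2, n_basis = 3, n_lag = 6, seed = 1,
                             zero_kernels = FALSE) {
  basis <- stapaw_basis(n_basis, n_lag)
  set.seed(seed)
  mk_em <- function() {
    kv <- function() if (zero_kernels) rep(0, n_basis) else
      round(stats::rnorm(n_basis, 0, 0.5), 3)
    emission_params(M = stats::runif(1, 0.3, 0.7),
                    m = stats::runif(1, 0.01, 0.1),
                    alpha = stats::runif(1, 0.05, 0.3),
                    kappa_turn = stats::runif(1, 1, 3),
                    kappa_wv = stats::runif(1, 3, 8),
                    k_C = kv(), k_h = kv(), k_dCp = kv(),
                    gamma_turn = c(2, 0.002), gamma_run = c(5, 0.001))
  }
  kernels <- if (Z > 1) {
    lapply(seq_len(Z), function(i) lapply(seq_len(Z), function(j) {
      if (i == j) NULL
      else if (zero_kernels) rep(0, n_basis)
      else round(stats::rnorm(n_basis, 0, 0.5), 3)
    }))
  } else NULL
  trans <- transition_params(Z, baseline = rep(1.5, Z), kernels = kernels)
  stapaw_params(Z = Z, dt = 5 / 14, basis = basis,
                emissions = replicate(Z, mk_em(), simplify = FALSE),
                transition = trans, init_dist = rep(1 / Z, Z))
}

# a random track with sensory series, for likelihood computations
make_random_track <- function(n = 50, seed = 2, with_I = FALSE) {
  set.seed(seed)
  heading <- cumsum(c(stats::runif(1, -pi, pi), stats::rnorm(n - 1, 0, 0.4)))
  dr <- stats::rgamma(n, 4, scale = 0.002)
  tr <- new_track("t1", dt = 5 / 14, t = seq_len(n) * 5 / 14,
                  x = cumsum(dr * cos(heading)), y = cumsum(dr * sin(heading)),
                  heading = wrap_angle(heading),
                  dtheta = wrap_angle(c(0, diff(heading))), dr = dr,
                  C = 25 + cumsum(stats::rnorm(n, 0, 0.1)),
                  dCp = stats::rnorm(n, 0, 0.2),
                  I = if (with_I) rbinom(n, 1, 0.2) else NULL)
  tr
}

# brute-force marginal log-likelihood by path enumeration
enumerate_loglik <- function(logB, A, pi0) {
  Tn <- nrow(logB); Z <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(Z)), Tn)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + logB[1, p[1]]
    if (Tn > 1)
      for (t in 2:Tn) v <- v + log(A[p[t - 1], p[t], t]) + logB[t, p[t]]
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

write_tracks_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Dirichlet(1,..,1) draw used to randomize initial distributions
rdirichlet1 <- function(Z) {
  x <- rexp(Z)
  x / sum(x)
}
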