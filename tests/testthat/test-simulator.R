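test_that("simulation is exactly reproducible from its seed", {
  p <- fixture_params("paperlike-2state")
  env <- env_linear()
  s1 <- simulate_stapaw(p, env, n_tracks = 2, n_steps = 150, seed = 9)
  s2 <- simulate_stapaw(p, env, n_tracks = 2, n_steps = 150, seed = 9)
  s3 <- simulate_stapaw(p, env, n_tracks = 2, n_steps = 150, seed = 10)
  expect_identical(s1$tracks[[1]]$x, s2$tracks[[1]]$x)
  expect_identical(s1$tracks[[2]]$z, s2$tracks[[2]]$z)
  expect_false(identical(s1$tracks[[1]]$x, s3$tracks[[1]]$x))
})

test_that("parameter limits produce straight runs with rare reversals", {
  # single state, no sensory drive, no uniform turns, high weathervane
  # concentration: straight runs broken only by rate-m reversals
  basis <- stapaw_basis(3, 6)
  em <- emission_params(M = 0.05, m = 0.05, alpha = 0, kappa_turn = 200,
                        kappa_wv = 200, k_C = rep(0, 3), k_h = rep(0, 3),
                        k_dCp = rep(0, 3), gamma_turn = c(50, 1e-4),
                        gamma_run = c(50, 1e-4))
  p <- stapaw_params(Z = 1, dt = 5 / 14, basis = basis,
                     emissions = list(em),
                     transition = transition_params(1, baseline = 0),
                     init_dist = 1)
  env <- env_linear(c0 = 25, slope = c(0, 0))
  sim <- simulate_stapaw(p, env, n_tracks = 4, n_steps = 500, seed = 3)
  dth <- unlist(lapply(sim$tracks, `[[`, "dtheta"))
  qs <- unlist(lapply(sim$tracks, `[[`, "q"))
  expect_lt(abs(mean(qs) - 0.05), 0.015)
  # non-turn steps are straight; turn steps are near-reversals
  expect_lt(max(abs(dth[qs == 0])), 0.5)
  expect_gt(min(abs(dth[qs == 1])), pi - 0.5)
  # speeds concentrate at the common Gamma mean
  expect_lt(abs(mean(unlist(lapply(sim$tracks, `[[`, "dr"))) - 50e-4),
            5e-4)
})

test_that("per-state turn frequency matches the analytic decision probability", {
  # zero all decision kernels so P(q=1|z) is the logistic midpoint
  p <- fixture_params("paperlike-2state")
  for (z in 1:2) {
    p$emissions[[z]]$k_C <- rep(0, 4)
    p$emissions[[z]]$k_h <- rep(0, 4)
  }
  env <- env_linear(c0 = 25, slope = c(0, 0))
  sim <- simulate_stapaw(p, env, n_tracks = 10, n_steps = 800, seed = 8)
  zs <- unlist(lapply(sim$tracks, `[[`, "z"))
  qs <- unlist(lapply(sim$tracks, `[[`, "q"))
  for (z in 1:2) {
    em <- p$emissions[[z]]
    expected <- em$m + (em$M - em$m) / 2
    n <- sum(zs == z)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(qs[zs == z]) - expected), 3 * se)
  }
})

test_that("fixture presets encode their documented structure", {
  ph <- fixture_params("hmm-2state")
  expect_identical(ph$transition$kernels[[1]][[2]], rep(0, 4))
  expect_identical(ph$transition$kernels[[2]][[1]], rep(0, 4))

  p1 <- fixture_params("dpaw-1state")
  expect_identical(p1$Z, 1L)

  po <- fixture_params("opto-2state")
  expect_false(is.null(po$transition$opto))
  expect_gt(sum(realized_weights(po$transition$opto[[1]][[2]], po$basis)), 0)

  p <- fixture_params("paperlike-2state")
  # mirror-shaped transition kernels with opposite signs
  wST <- realized_weights(p$transition$kernels[[1]][[2]], p$basis)
  wTS <- realized_weights(p$transition$kernels[[2]][[1]], p$basis)
  expect_lt(sum(wST * wTS) / sqrt(sum(wST^2) * sum(wTS^2)), -0.99)
  # trend detectors: realized weights sum to ~0
  expect_lt(abs(sum(wST)), 1e-8)

  pf <- fixture_params("paperlike-2state", flip_transition_sign = TRUE)
  expect_equal(realized_weights(pf$transition$kernels[[1]][[2]], p$basis),
               -wST)
})

test_that("sensory-free dwell times follow the geometric baseline targets", {
  p <- fixture_params("paperlike-2state")
  env0 <- env_linear(c0 = 25, slope = c(0, 0))  # no sensory drive
  sim <- simulate_stapaw(p, env0, n_tracks = 10, n_steps = 1200, seed = 5)
  zs <- unlist(lapply(sim$tracks, `[[`, "z"))
  r <- rle(zs)
  dwell <- tapply(r$lengths, r$values, mean) * p$dt
  expected <- p$dt / (1 - plogis(p$transition$baseline))
  expect_equal(unname(dwell[1]), expected[1], tolerance = 0.2 * expected[1])
  expect_equal(unname(dwell[2]), expected[2], tolerance = 0.2 * expected[2])
  # seconds-scale and steer-state longer-lived than turn-state
  expect_gt(dwell[1], dwell[2])
})

test_that("open-loop sampling respects fixed input and ignores absent stimulus", {
  p <- fixture_params("opto-2state")
  Tn <- 400
  C <- rep(25, Tn)
  # all-zero stimulus gives draws identical to no stimulus at equal seed
  a <- simulate_open_loop(p, C, I = rep(0, Tn), seed = 4)
  b <- simulate_open_loop(p, C, I = NULL, seed = 4)
  expect_identical(a$z, b$z)
  expect_identical(a$dtheta, b$dtheta)
  expect_error(simulate_open_loop(p, C, I = rep(0, 10)), "length mismatch")
})

test_that("pulsed stimulation raises turn-state occupancy during pulses", {
  p <- fixture_params("opto-2state")
  n_pulses <- 120
  win <- 14          # 5 s measurement window at 5/14 s steps
  on_len <- 28; off_len <- 56
  period <- on_len + off_len
  Tn <- n_pulses * period
  I <- rep(c(rep(1, on_len), rep(0, off_len)), n_pulses)
  C <- rep(25, Tn)
  out <- simulate_open_loop(p, C, I = I, seed = 6)
  starts <- (0:(n_pulses - 1)) * period
  on_idx <- as.vector(outer((on_len - win + 1):on_len, starts, "+"))
  post_idx <- as.vector(outer((on_len + 1):(on_len + win), starts, "+"))
  base_idx <- as.vector(outer((period - win + 1):period, starts, "+"))
  p_on <- mean(out$z[on_idx] == 2)
  p_post <- mean(out$z[post_idx] == 2)
  p_base <- mean(out$z[base_idx] == 2)
  expect_gt(p_on, p_post)
  expect_gt(p_post, p_base)  # slow relaxation after light off
})
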