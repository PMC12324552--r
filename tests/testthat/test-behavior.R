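mk_track_dtheta <- function(dtheta_deg, dt = 5 / 14) {
  n <- length(dtheta_deg)
  dth <- dtheta_deg * pi / 180
  heading <- cumsum(dth)
  new_track("b", dt = dt, t = seq_len(n) * dt,
            x = cumsum(0.01 * cos(heading)), y = cumsum(0.01 * sin(heading)),
            heading = wrap_angle(heading), dtheta = wrap_angle(dth),
            dr = rep(0.01, n))
}

test_that("turn detection registers onsets above the threshold", {
  tr <- mk_track_dtheta(c(10, 60, 55, 20, -80))
  ev <- detect_turns(tr)
  expect_identical(ev$events, c(2L, 5L))
  expect_equal(ev$threshold_deg, 50)

  # all sub-threshold: no events
  expect_length(detect_turns(mk_track_dtheta(rep(30, 10)))$events, 0)
})

test_that("inter-turn intervals pool within tracks only", {
  t1 <- detect_turns(mk_track_dtheta(c(10, 60, 55, 20, -80)))
  expect_equal(inter_turn_intervals(t1), 3 * 5 / 14)
  # single event contributes nothing
  t2 <- detect_turns(mk_track_dtheta(c(10, 60, 10, 10, 10)))
  expect_length(inter_turn_intervals(list(t2)), 0)
  expect_equal(inter_turn_intervals(list(t1, t2)), 3 * 5 / 14)
})

test_that("exponential fits recover generating rates", {
  set.seed(101)
  # one-rate samples: single fit finds the rate; double degenerates
  x1 <- rexp(5000, rate = 1)
  f1 <- fit_exponentials(x1, "single")
  expect_equal(f1$rates, 1, tolerance = 0.1)
  f1d <- fit_exponentials(x1, "double")
  degenerate <- abs(log(f1d$rates[1] / f1d$rates[2])) < log(2.5) ||
    min(f1d$weights) < 0.05
  expect_true(degenerate)

  # half-and-half mixture of rates 1.0 and 0.1
  x2 <- c(rexp(5000, 1), rexp(5000, 0.1))
  f2 <- fit_exponentials(x2, "double")
  expect_lt(abs(sort(f2$rates)[1] - 0.1) / 0.1, 0.2)
  expect_lt(abs(sort(f2$rates)[2] - 1) / 1, 0.2)
  f2s <- fit_exponentials(x2, "single")
  expect_gt(f2$r_squared, f2s$r_squared)
  # crossing time of an even mixture: log(l1/l2)/(l1 - l2)
  tc_true <- log(1 / 0.1) / (1 - 0.1)
  expect_equal(f2$t_c, tc_true, tolerance = 0.1 * tc_true)

  # Poisson-turn process: the single-exponential fit recovers the rate
  set.seed(7)
  p_turn <- 0.1
  dth <- ifelse(runif(8000) < p_turn, 120, 5)
  ev <- detect_turns(mk_track_dtheta(dth))
  iti <- inter_turn_intervals(ev)
  fp <- fit_exponentials(iti, "single")
  expect_lt(abs(fp$rates - p_turn / (5 / 14)) / (p_turn / (5 / 14)), 0.2)
})

test_that("speed autocorrelation separates white noise from AR(1)", {
  dt <- 5 / 14
  mk_dr <- function(dr) {
    n <- length(dr)
    new_track("s", dt = dt, t = seq_len(n) * dt, x = cumsum(dr),
              y = rep(0, n), heading = rep(0, n), dtheta = rep(0, n),
              dr = dr)
  }
  set.seed(11)
  white <- replicate(4, mk_dr(abs(rnorm(2000, 1, 0.2))), simplify = FALSE)
  aw <- speed_autocorrelation(white, max_lag = 20)
  expect_equal(aw$acf[1], 1)
  expect_lt(max(abs(aw$acf[-1])), 0.1)

  rho <- 0.8
  ar <- replicate(4, {
    x <- as.numeric(arima.sim(list(ar = rho), 3000)) + 10
    mk_dr(abs(x))
  }, simplify = FALSE)
  aa <- speed_autocorrelation(ar, max_lag = 25)
  # decay rate ~ -log(rho) per step
  expect_equal(aa$fit_single$rates * dt, -log(rho), tolerance = 0.15)
})

test_that("classical pirouette identification merges turns closer than t_c", {
  dt <- 5 / 14
  tc <- 6.8
  gap_steps <- function(s) round(s / dt)
  # turns at 0 s and 3 s -> one bout; 0 s and 10 s -> two bouts
  ev1 <- structure(list(events = c(10L, 10L + gap_steps(3)),
                        threshold_deg = 50, n_steps = 60L, dt = dt),
                   class = "stapaw_turns")
  b1 <- identify_pirouettes_classical(ev1, tc)
  expect_identical(nrow(b1$bouts), 1L)
  expect_true(all(b1$mask[ev1$events[1]:ev1$events[2]]))

  ev2 <- structure(list(events = c(10L, 10L + gap_steps(10)),
                        threshold_deg = 50, n_steps = 60L, dt = dt),
                   class = "stapaw_turns")
  b2 <- identify_pirouettes_classical(ev2, tc)
  expect_identical(nrow(b2$bouts), 2L)

  ev0 <- structure(list(events = integer(0), threshold_deg = 50,
                        n_steps = 20L, dt = dt), class = "stapaw_turns")
  b0 <- identify_pirouettes_classical(ev0, tc)
  expect_false(any(b0$mask))
})

test_that("bearing analyses behave at their symmetry points", {
  env <- env_linear()
  # synthetic tracks with prescribed bearings at forced exits
  mk_btrack <- function(bearings_deg, states) {
    n <- length(states)
    heading <- (0 - bearings_deg) * pi / 180  # gradient along +x
    tr <- new_track("bt", dt = 5 / 14, t = seq_len(n) * 5 / 14,
                    x = seq(2, 3, length.out = n), y = rep(4, n),
                    heading = heading, dtheta = rep(0, n),
                    dr = rep(0.005, n))
    tr <- extract_sensory(tr, env)
    tr$z <- states
    tr
  }
  # all exits exactly upgradient -> aligned fraction 1
  states <- rep(c(2L, 2L, 1L, 1L), 10)
  tr <- mk_btrack(rep(0, length(states)), states)
  out <- bearing_at_transitions(list(tr), mode = "exit",
                                resample_size = 10, n_resample = 5)
  expect_equal(out$aligned_fraction, 1)
  expect_equal(out$n_events, sum(states[-length(states)] == 2 &
                                   states[-1] == 1))

  # uniform headings at exit -> aligned fraction near 0.5
  set.seed(3)
  trs <- lapply(1:20, function(k)
    mk_btrack(runif(length(states), 0, 180), states))
  out2 <- bearing_at_transitions(trs, mode = "exit",
                                 resample_size = 100, n_resample = 10)
  expect_lt(abs(out2$aligned_fraction - 0.5), 0.08)
  expect_error(bearing_at_transitions(list(mk_btrack(rep(0, 4),
                                                     rep(1L, 4)))),
               "no transition events")
})

test_that("shuffled-exit control is seeded and a no-op for equal angles", {
  env <- env_linear()
  set.seed(21)
  p <- fixture_params("paperlike-2state")
  sim <- simulate_stapaw(p, env, n_tracks = 3, n_steps = 400, seed = 15)
  sim$tracks <- lapply(sim$tracks, extract_sensory, env = env)
  s1 <- shuffled_exit_control(sim$tracks, env, seed = 1)
  s2 <- shuffled_exit_control(sim$tracks, env, seed = 1)
  expect_identical(s1$bearing, s2$bearing)

  # identical turn angles everywhere: permutation changes nothing
  n <- 60
  dth <- rep(c(rep(0.05, 9), 2), 6)
  heading <- cumsum(dth)
  tr <- new_track("e", dt = 5 / 14, t = seq_len(n) * 5 / 14,
                  x = 3 + cumsum(0.004 * cos(heading)),
                  y = 3 + cumsum(0.004 * sin(heading)),
                  heading = wrap_angle(heading), dtheta = wrap_angle(dth),
                  dr = rep(0.004, n))
  tr <- extract_sensory(tr, env)
  ev <- detect_turns(tr)
  base <- tr$bearing[ev$events]
  sh <- shuffled_exit_control(list(tr), env, seed = 2)
  expect_equal(sort(round(sh$bearing, 6)), sort(round(base, 6)))
})

test_that("chemotaxis index is the fraction of tracks ending near the source", {
  mk_end <- function(x, y) {
    new_track("c", dt = 1, t = 1:2, x = c(0, x), y = c(0, y),
              heading = c(0, 0), dtheta = c(0, 0), dr = c(1, 1))
  }
  tracks <- list(mk_end(0.1, 0), mk_end(3, 0), mk_end(0, 0.4))
  expect_equal(chemotaxis_index(tracks, c(0, 0), 0.5), 2 / 3)
  expect_equal(chemotaxis_index(tracks, c(10, 10), 0.5), 0)

  # uniform endpoints in a disk of radius R, target R/2: CI ~ 1/4
  set.seed(9)
  r <- sqrt(runif(4000)); th <- runif(4000, 0, 2 * pi)
  finals <- cbind(r * cos(th), r * sin(th))
  expect_equal(chemotaxis_index(finals, c(0, 0), 0.5), 0.25,
               tolerance = 0.03)
})
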