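test_that("read_tracks parses, groups and validates trajectory tables", {
  path <- write_tracks_csv(data.frame(
    track_id = c("a", "a"), t = c(0, 1), x = c(0, 1), y = c(0, 0)))
  out <- read_tracks(path)
  expect_length(out, 1)
  expect_length(out[[1]]$x, 2)

  # interleaved ids split into two trajectories, each time-sorted
  path2 <- write_tracks_csv(data.frame(
    track_id = c("a", "b", "a", "b"), t = c(0, 0.5, 1, 0),
    x = 1:4, y = 0))
  out2 <- read_tracks(path2)
  expect_length(out2, 2)
  expect_true(all(diff(out2[[2]]$t) > 0))

  # duplicate timestamp in a track is a data error naming the track
  path3 <- write_tracks_csv(data.frame(
    track_id = "a", t = c(0, 1, 1), x = 1:3, y = 0))
  expect_error(read_tracks(path3), "non-monotone.*a")

  # schema errors
  expect_error(read_tracks(path, schema = c(track_id = "nope", t = "t",
                                            x = "x", y = "y")),
               "not found")
  expect_error(read_tracks(path, schema = c(t = "t", x = "x", y = "y")),
               "schema missing")
  expect_error(read_tracks(tempfile()), "file not found")
})

test_that("preprocess turns straight constant-speed motion into flat kinematics", {
  v <- 0.02  # cm/s
  raw <- make_straight_raw(n = 140, vx = v)
  tr <- preprocess(raw, smooth_window = 5, downsample = 5)
  expect_equal(tr$dt, 5 / 14)
  expect_true(all(abs(tr$dtheta) < 1e-9))
  expect_equal(tr$dr, rep(v * 5 / 14, track_length(tr)), tolerance = 1e-8)
})

test_that("preprocess captures a single 90-degree turn", {
  # no smoothing so the corner stays sharp; downsample 1
  n <- 30
  x <- c(seq(0, 1, length.out = n), rep(1, n - 1))
  y <- c(rep(0, n), seq(0, 1, length.out = n)[-1])
  raw <- raw_trajectory("L", seq_along(x) / 14, x, y)
  tr <- preprocess(raw, smooth_window = 1, downsample = 1)
  expect_equal(sum(abs(tr$dtheta) > 1e-6), 1)
  expect_equal(max(tr$dtheta), pi / 2, tolerance = 1e-8)  # CCW positive
})

test_that("preprocess rejects too-short tracks", {
  raw <- make_straight_raw(n = 12)
  expect_error(preprocess(raw, downsample = 5), "too short")
})

test_that("filter_tracks applies the area and duration rules", {
  mk <- function(extent, n, id) {
    th <- seq(0, 2 * pi, length.out = n)
    new_track(id, dt = 5 / 14, t = seq_len(n) * 5 / 14,
              x = extent * cos(th), y = extent * sin(th),
              heading = th, dtheta = rep(0.01, n), dr = rep(0.005, n))
  }
  ten_min <- round(600 / (5 / 14))
  two_min <- round(120 / (5 / 14))
  stationary <- mk(1e-4, ten_min, "still")    # area ~ 0, long
  short <- mk(1, two_min, "short")            # 4 cm^2, 2 min
  good <- mk(1, ten_min, "good")              # 4 cm^2, 10 min
  ds <- filter_tracks(list(stationary, short, good), quiet = TRUE)
  expect_length(ds$tracks, 1)
  expect_identical(ds$tracks[[1]]$track_id, "good")
  expect_identical(attr(ds, "n_removed"), 2L)
  expect_error(filter_tracks(list(stationary), quiet = TRUE), "all tracks")
})

test_that("extract_sensory computes bearing and perpendicular difference", {
  env <- env_linear(c0 = 0, slope = c(50 / 9, 0), bounds = c(0, 9, 0, 9))
  base <- function(heading) {
    new_track("s", dt = 5 / 14, t = 1:3, x = c(4, 4.1, 4.2),
              y = c(4, 4, 4), heading = rep(heading, 3),
              dtheta = rep(0, 3), dr = rep(0.1, 3))
  }
  up <- extract_sensory(base(0), env)       # heading along +x = upgradient
  expect_equal(up$bearing, rep(0, 3), tolerance = 1e-8)
  expect_equal(up$dCp, rep(0, 3), tolerance = 1e-10)

  # heading +y: gradient (+x) points to the right -> dCp < 0, B = 90
  perp <- extract_sensory(base(pi / 2), env)
  expect_equal(perp$bearing, rep(90, 3), tolerance = 1e-8)
  expect_true(all(perp$dCp < 0))
  # gradient to the left (heading -y) -> dCp > 0
  perp2 <- extract_sensory(base(-pi / 2), env)
  expect_true(all(perp2$dCp > 0))

  # uniform field: constant C, zero dCp, undefined bearing
  env0 <- env_linear(c0 = 3, slope = c(0, 0))
  u <- extract_sensory(base(0.7), env0)
  expect_equal(u$C, rep(3, 3))
  expect_equal(u$dCp, rep(0, 3))
  expect_true(all(is.na(u$bearing)))
})

test_that("kinematics are invariant to rigid rotation and flip under time reversal", {
  set.seed(5)
  n <- 199  # odd length so down-sampling phases match under reversal
  steps <- cbind(stats::rnorm(n, 0, 0.02), stats::rnorm(n, 0, 0.02))
  xy <- apply(steps, 2, cumsum)
  raw <- raw_trajectory("r", seq_len(n) / 14, xy[, 1], xy[, 2])
  tr <- preprocess(raw, smooth_window = 3, downsample = 2)

  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  xyr <- xy %*% t(R)
  trr <- preprocess(raw_trajectory("r2", seq_len(n) / 14, xyr[, 1], xyr[, 2]),
                    smooth_window = 3, downsample = 2)
  expect_equal(trr$dr, tr$dr, tolerance = 1e-10)
  expect_equal(trr$dtheta, tr$dtheta, tolerance = 1e-10)

  # time reversal: dr preserved, dtheta negated, as multisets up to the
  # few boundary steps that preprocessing drops at (different) track ends
  trf <- preprocess(raw, smooth_window = 1, downsample = 2)
  trv <- preprocess(raw_trajectory("r3", seq_len(n) / 14, rev(xy[, 1]),
                                   rev(xy[, 2])),
                    smooth_window = 1, downsample = 2)
  unmatched <- function(a, b) sum(is.na(match(round(a, 10), round(b, 10))))
  expect_lte(unmatched(trv$dr, trf$dr), 3)
  expect_lte(unmatched(wrap_angle(-trv$dtheta), trf$dtheta), 3)
})

test_that("dCp in a linear gradient equals the analytic 2 offset |grad| sin(B)", {
  env <- env_linear(c0 = 0, slope = c(2, 1), bounds = c(-50, 50, -50, 50))
  off <- 0.05
  gmag <- sqrt(sum(env$slope^2))
  grad_angle <- atan2(env$slope[2], env$slope[1])
  for (h in seq(-pi, pi, length.out = 9)) {
    tr <- new_track("a", dt = 1, t = 1, x = 0.5, y = 0.5, heading = h,
                    dtheta = 0, dr = 0.1)
    tr <- extract_sensory(tr, env, sensor_offset = off)
    b_signed <- wrap_angle(grad_angle - h)
    expect_equal(tr$dCp, gmag * 2 * off * sin(b_signed), tolerance = 1e-9)
  }
})
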