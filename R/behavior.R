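# Descriptive behavioral statistics: turn detection, inter-turn intervals
# and their exponential fits, speed autocorrelation, classical pirouette
# identification, bearing-at-transition analyses, and the chemotaxis index.

#' Detect turn events in a track
#'
#' A turn event is registered at each onset step where |dtheta| first
#' crosses above the threshold; consecutive supra-threshold steps yield a
#' single event at the first of them.
#'
#' @param track a `stapaw_track`.
#' @param threshold_deg turn threshold in degrees (default 50).
#' @return an object of class `stapaw_turns`: list with `events` (step
#'   indices, 1-based) and `threshold_deg`.
#' @export
detect_turns <- function(track, threshold_deg = 50) {
  stopifnot(threshold_deg > 0)
  above <- abs(track$dtheta) > threshold_deg * pi / 180
  onset <- above & !c(FALSE, above[-length(above)])
  structure(list(events = which(onset), threshold_deg = threshold_deg,
                 n_steps = track_length(track), dt = track$dt),
            class = "stapaw_turns")
}

#' Pooled inter-turn intervals
#'
#' Successive differences of event times within each track (intervals never
#' span tracks), pooled across tracks, in seconds.
#'
#' @param events a `stapaw_turns` or list of them.
#' @param dt seconds per step; defaults to the value recorded on events.
#' @return numeric vector of interval samples (s).
#' @export
inter_turn_intervals <- function(events, dt = NULL) {
  if (inherits(events, "stapaw_turns")) events <- list(events)
  unlist(lapply(events, function(ev) {
    if (length(ev$events) < 2) return(numeric(0))
    diff(ev$events) * (dt %||% ev$dt)
  }))
}

#' Fit single- or double-exponential models to interval samples
#'
#' Bins the samples into log-spaced bins, normalizes to a density, and
#' fits `lambda exp(-lambda t)` (single) or the two-component mixture
#' `w l1 exp(-l1 t) + (1 - w) l2 exp(-l2 t)` (double) by nonlinear least
#' squares, with multi-start on failure. R^2 is computed on the binned
#' density. For the double fit, `t_c` is the crossing time where the two
#' weighted components are equal.
#'
#' @param samples positive interval samples (>= 50).
#' @param model `"single"` or `"double"`.
#' @param n_bins number of log-spaced bins (default 32).
#' @return an object of class `stapaw_expfit`: list with `model`, `rates`
#'   (1/s, decreasing), `weights`, `r_squared`, and `t_c` (double only).
#' @export
fit_exponentials <- function(samples, model = c("single", "double"),
                             n_bins = 32) {
  model <- match.arg(model)
  samples <- samples[is.finite(samples) & samples > 0]
  if (length(samples) < 50)
    stop("need at least 50 interval samples", call. = FALSE)
  brk <- exp(seq(log(min(samples) * 0.999), log(max(samples) * 1.001),
                 length.out = n_bins + 1))
  h <- graphics::hist(samples, breaks = brk, plot = FALSE)
  keep <- h$counts > 0
  tmid <- h$mids[keep]
  dens <- h$density[keep]
  fit_curve_exponentials(tmid, dens, model, normalized = TRUE)
}

# Shared least-squares machinery for density curves (y ~ sum of
# exponentials). With normalized = TRUE components are densities
# (w l exp(-l t), weights summing to 1) and the fit and R^2 are computed
# on the log density, which spans the decades of a heavy-tailed interval
# histogram evenly; otherwise plain amplitudes exp(-l t) weighted by w
# summing to 1 are fit on the linear scale (autocorrelation curves).
fit_curve_exponentials <- function(tmid, y, model, normalized) {
  if (normalized) y <- log(pmax(y, 1e-300))
  tf <- if (normalized) function(v) log(pmax(v, 1e-300)) else identity
  r2 <- function(pred) 1 - sum((y - tf(pred))^2) / sum((y - mean(y))^2)
  mrate <- 1 / max(mean(tmid), 1e-9)
  if (model == "single") {
    f1raw <- function(l) if (normalized) l * exp(-l * tmid) else exp(-l * tmid)
    f1 <- function(l) tf(f1raw(l))
    best <- NULL
    for (l0 in mrate * c(0.3, 1, 3)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ f1(exp(loglam)),
                          start = list(loglam = log(l0)),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
    if (is.null(best)) stop("single-exponential fit failed", call. = FALSE)
    lam <- exp(stats::coef(best$fit)[["loglam"]])
    return(structure(list(model = "single", rates = lam, weights = 1,
                          r_squared = r2(f1raw(lam))),
                     class = "stapaw_expfit"))
  }
  f2raw <- function(l1, l2, w) {
    if (normalized) w * l1 * exp(-l1 * tmid) + (1 - w) * l2 * exp(-l2 * tmid)
    else w * exp(-l1 * tmid) + (1 - w) * exp(-l2 * tmid)
  }
  f2 <- function(l1, l2, w) tf(f2raw(l1, l2, w))
  best <- NULL
  for (sp in list(c(3, 0.3, 0), c(10, 0.5, 0.8), c(1, 0.1, -0.8),
                  c(5, 1, 0.5))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f2(exp(l1), exp(l2), stats::plogis(lw)),
        start = list(l1 = log(mrate * sp[1]), l2 = log(mrate * sp[2]),
                     lw = sp[3]),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("double-exponential fit failed", call. = FALSE)
  cf <- stats::coef(best$fit)
  l <- exp(c(cf[["l1"]], cf[["l2"]]))
  w <- c(stats::plogis(cf[["lw"]]), 1 - stats::plogis(cf[["lw"]]))
  ord <- order(l, decreasing = TRUE)  # fast rate first
  l <- l[ord]; w <- w[ord]
  # crossing time of the two weighted components
  tc <- if (abs(l[1] - l[2]) < 1e-9) NA_real_ else {
    amp <- if (normalized) w * l else w
    log(amp[1] / amp[2]) / (l[1] - l[2])
  }
  structure(list(model = "double", rates = l, weights = w,
                 r_squared = r2(f2raw(l[1], l[2], w[1])), t_c = tc),
            class = "stapaw_expfit")
}

#' @export
print.stapaw_expfit <- function(x, ...) {
  cat(sprintf("<%s-exponential fit: rates %s /s, R^2 = %.3f%s>\n",
              x$model, paste(signif(x$rates, 3), collapse = ", "),
              x$r_squared,
              if (!is.null(x$t_c) && is.finite(x$t_c))
                sprintf(", t_c = %.2f s", x$t_c) else ""))
  invisible(x)
}

#' Speed autocorrelation with exponential fits
#'
#' Mean-removed, lag-0-normalized autocorrelation of the step displacement,
#' computed per track and averaged, with single and double exponential
#' fits to the decay.
#'
#' @param tracks a `stapaw_dataset` or list of tracks.
#' @param max_lag maximum lag in steps (default 40).
#' @return list with `lag_s`, `acf`, `fit_single`, `fit_double`.
#' @export
speed_autocorrelation <- function(tracks, max_lag = 40) {
  if (inherits(tracks, "stapaw_dataset")) tracks <- tracks$tracks
  dt <- tracks[[1]]$dt
  acs <- sapply(tracks, function(tr) {
    a <- stats::acf(tr$dr, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a / a[1]
  })
  ac <- rowMeans(acs)
  lag_s <- (0:max_lag) * dt
  keep <- lag_s > 0
  fs <- fit_curve_exponentials(lag_s[keep], ac[keep], "single",
                               normalized = FALSE)
  fd <- tryCatch(
    fit_curve_exponentials(lag_s[keep], ac[keep], "double",
                           normalized = FALSE),
    error = function(e) fs)
  list(lag_s = lag_s, acf = ac, fit_single = fs, fit_double = fd)
}

#' Classical pirouette identification
#'
#' Merges turns separated by less than `t_c` seconds into pirouette bouts
#' spanning first-to-last turn; isolated turns form single-step bouts.
#'
#' @param events a `stapaw_turns` object.
#' @param t_c merging threshold in seconds (classically the crossing time
#'   of the double-exponential interval fit).
#' @return list with `mask` (per-step logical) and `bouts` (data frame
#'   with start/end step indices and turn counts).
#' @export
identify_pirouettes_classical <- function(events, t_c) {
  stopifnot(inherits(events, "stapaw_turns"), t_c > 0)
  ev <- events$events
  mask <- rep(FALSE, events$n_steps)
  if (length(ev) == 0)
    return(list(mask = mask,
                bouts = data.frame(start = integer(0), end = integer(0),
                                   n_turns = integer(0))))
  gap_steps <- t_c / events$dt
  grp <- cumsum(c(1, diff(ev) >= gap_steps))
  starts <- tapply(ev, grp, min)
  ends <- tapply(ev, grp, max)
  n_turns <- tapply(ev, grp, length)
  for (k in seq_along(starts)) mask[starts[k]:ends[k]] <- TRUE
  list(mask = mask,
       bouts = data.frame(start = as.integer(starts), end = as.integer(ends),
                          n_turns = as.integer(n_turns)))
}

#' Bearings at state entries or exits
#'
#' Collects the bearing (degrees, 0 = upgradient) at each entry to or exit
#' from a reference state, either per state bout or per single turn, and
#' summarizes the aligned fraction P(B < 90 deg) with a resampling
#' uncertainty (50 subsamples of 2000 events by default).
#'
#' @param tracks a `stapaw_dataset`/`stapaw_sim` or list of tracks with
#'   `bearing` attached (see [extract_sensory()]).
#' @param states list of per-track state series (integer; or logical
#'   pirouette masks), aligned to the tracks. Defaults to the tracks' own
#'   latent `z` when present.
#' @param mode `"exit"` or `"enter"`.
#' @param unit `"state-bout"` (transitions of the state series) or
#'   `"single-turn"` (detected turn events; `states` is ignored).
#' @param state index regarded as the turn state (default: the largest
#'   state label).
#' @param threshold_deg turn threshold for `unit = "single-turn"`.
#' @param n_resample,resample_size resampling scheme for the aligned
#'   fraction standard deviation.
#' @param seed seed for the resampling.
#' @return list with `bearing` (samples, degrees), `aligned_fraction`,
#'   `aligned_sd`, `n_events`.
#' @export
bearing_at_transitions <- function(tracks, states = NULL,
                                   mode = c("exit", "enter"),
                                   unit = c("state-bout", "single-turn"),
                                   state = NULL, threshold_deg = 50,
                                   n_resample = 50, resample_size = 2000,
                                   seed = 0) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (inherits(tracks, "stapaw_dataset")) tracks <- tracks$tracks
  bearings <- c()
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    if (is.null(tr$bearing))
      stop("tracks need bearing series; run extract_sensory() first",
           call. = FALSE)
    if (unit == "single-turn") {
      ev <- detect_turns(tr, threshold_deg)$events
      # bearing right at the turn step (heading already includes the turn)
      idx <- if (mode == "exit") ev else pmax(ev - 1L, 1L)
    } else {
      s <- if (!is.null(states)) states[[k]] else tr$z
      if (is.null(s))
        stop("no state series available for track ", k, call. = FALSE)
      if (is.logical(s)) s <- as.integer(s) + 1L
      ref <- state %||% max(s)
      inref <- s == ref
      n <- length(s)
      idx <- if (mode == "exit") {
        which(inref[-n] & !inref[-1])        # last step inside the state
      } else {
        which(!inref[-n] & inref[-1]) + 1L   # first step inside the state
      }
    }
    bearings <- c(bearings, tr$bearing[idx])
  }
  bearings <- bearings[is.finite(bearings)]
  if (length(bearings) == 0) stop("no transition events found", call. = FALSE)
  aligned <- mean(bearings < 90)
  sdev <- with_seed(sub_seed(seed, 77L), {
    stats::sd(replicate(n_resample, {
      mean(sample(bearings, resample_size, replace = TRUE) < 90)
    }))
  })
  list(bearing = bearings, aligned_fraction = aligned, aligned_sd = sdev,
       n_events = length(bearings))
}

#' Exit bearings under shuffled turn angles
#'
#' Control for directed exits: permutes the heading-change values at turn
#' events across all events (seeded), rebuilds headings by cumulative
#' summation, and returns the bearing at each event under the original
#' positions' local gradients.
#'
#' @param tracks dataset or list of tracks with sensory series.
#' @param env the environment (for local gradient directions).
#' @param threshold_deg turn threshold.
#' @param seed permutation seed.
#' @return list with `bearing` samples (degrees) and `aligned_fraction`.
#' @export
shuffled_exit_control <- function(tracks, env, threshold_deg = 50, seed = 0) {
  if (inherits(tracks, "stapaw_dataset")) tracks <- tracks$tracks
  evs <- lapply(tracks, detect_turns, threshold_deg = threshold_deg)
  pool_idx <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    if (length(evs[[k]]$events) == 0) return(NULL)
    cbind(k, evs[[k]]$events)
  }))
  if (is.null(pool_idx)) stop("no turn events to shuffle", call. = FALSE)
  angles <- mapply(function(k, i) tracks[[k]]$dtheta[i],
                   pool_idx[, 1], pool_idx[, 2])
  perm <- with_seed(sub_seed(seed, 99L), sample(length(angles)))
  shuffled <- angles[perm]
  bearings <- c()
  ptr <- 1
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    ev <- evs[[k]]$events
    if (length(ev) == 0) next
    dth <- tr$dtheta
    dth[ev] <- shuffled[ptr:(ptr + length(ev) - 1)]
    ptr <- ptr + length(ev)
    heading0 <- tr$heading[1] - tr$dtheta[1]
    new_heading <- wrap_angle(heading0 + cumsum(dth))
    g <- env_gradient(env, cbind(tr$x, tr$y))
    ga <- atan2(g[, 2], g[, 1])
    b <- abs(wrap_angle(ga - new_heading)) * 180 / pi
    bearings <- c(bearings, b[ev])
  }
  bearings <- bearings[is.finite(bearings)]
  list(bearing = bearings, aligned_fraction = mean(bearings < 90))
}

#' Chemotaxis index
#'
#' Fraction of tracks whose final position lies within `radius` of the
#' source.
#'
#' @param tracks dataset or list of tracks (or n x 2 matrix of final
#'   positions).
#' @param source length-2 source position, cm.
#' @param radius success radius, cm (> 0).
#' @return fraction in [0, 1].
#' @export
chemotaxis_index <- function(tracks, source, radius) {
  stopifnot(radius > 0, length(source) == 2)
  finals <- if (is.matrix(tracks)) tracks else {
    if (inherits(tracks, "stapaw_dataset")) tracks <- tracks$tracks
    t(vapply(tracks, function(tr)
      c(utils::tail(tr$x, 1), utils::tail(tr$y, 1)), numeric(2)))
  }
  d <- sqrt((finals[, 1] - source[1])^2 + (finals[, 2] - source[2])^2)
  mean(d <= radius)
}
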