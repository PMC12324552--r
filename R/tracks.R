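# Trajectory I/O, preprocessing and sensory feature extraction.
#
# Raw input is a long-format table of centroid positions (track_id, t, x, y,
# optional stimulus column I) sampled at the camera frame rate (14 Hz by
# default). Preprocessing smooths, down-samples, and converts positions to
# per-step kinematics: heading, heading change dtheta (radians, CCW
# positive, wrapped to (-pi, pi]) and step displacement dr (cm).

#' Read centroid trajectories from a table file
#'
#' @param path CSV file with one row per frame.
#' @param schema named character vector mapping the roles `track_id`, `t`,
#'   `x`, `y` (and optionally `I`) to column names in the file.
#' @param frame_rate sampling rate in Hz (default 14).
#' @return list of raw trajectories (class `stapaw_raw`), one per track id,
#'   each sorted by time.
#' @export
read_tracks <- function(path,
                        schema = c(track_id = "track_id", t = "t",
                                   x = "x", y = "y"),
                        frame_rate = 14) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t", "x", "y")
  missing_roles <- setdiff(need, names(schema))
  if (length(missing_roles) > 0)
    stop("schema missing roles: ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(tab))
  if (length(missing_cols) > 0)
    stop("columns not found in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  has_I <- "I" %in% names(schema) && schema[["I"]] %in% names(tab)
  ids <- unique(tab[[schema[["track_id"]]]])
  out <- lapply(ids, function(id) {
    rows <- tab[tab[[schema[["track_id"]]]] == id, , drop = FALSE]
    rows <- rows[order(rows[[schema[["t"]]]]), , drop = FALSE]
    tt <- rows[[schema[["t"]]]]
    if (any(diff(tt) <= 0))
      stop("non-monotone time in track ", id, call. = FALSE)
    raw_trajectory(track_id = id, t = tt,
                   x = rows[[schema[["x"]]]], y = rows[[schema[["y"]]]],
                   I = if (has_I) rows[[schema[["I"]]]] else NULL,
                   frame_rate = frame_rate)
  })
  out
}

#' Construct a raw trajectory
#'
#' @param track_id identifier.
#' @param t time stamps in seconds, strictly increasing.
#' @param x,y centroid positions in cm.
#' @param I optional per-frame stimulus series.
#' @param frame_rate sampling rate in Hz.
#' @return an object of class `stapaw_raw`.
#' @export
raw_trajectory <- function(track_id, t, x, y, I = NULL, frame_rate = 14) {
  stopifnot(length(t) >= 2, length(x) == length(t), length(y) == length(t))
  if (any(diff(t) <= 0))
    stop("non-monotone time in track ", track_id, call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite positions in track ", track_id, call. = FALSE)
  if (!is.null(I)) stopifnot(length(I) == length(t))
  structure(list(track_id = track_id, t = as.numeric(t), x = as.numeric(x),
                 y = as.numeric(y), I = I, frame_rate = frame_rate),
            class = "stapaw_raw")
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  y <- stats::filter(x, k, method = "convolution", sides = 2)
  y <- as.numeric(y)
  # centered window is undefined at the edges; keep raw values there
  y[!is.finite(y)] <- x[!is.finite(y)]
  y
}

#' Preprocess a raw trajectory into per-step kinematics
#'
#' Positions are smoothed with a centered moving average, kept every
#' `downsample`-th frame, and differenced into heading, heading change and
#' step displacement. The first two down-sampled steps, where derivatives
#' are undefined, are dropped.
#'
#' @param raw a `stapaw_raw` trajectory.
#' @param smooth_window moving-average window in raw frames (default 5).
#' @param downsample integer down-sampling factor (default 5; 14 Hz input
#'   gives one data point every 5/14 s).
#' @return an object of class `stapaw_track` with fields `t`, `x`, `y`,
#'   `heading`, `dtheta`, `dr`, optional `I`, and step duration `dt`.
#' @export
preprocess <- function(raw, smooth_window = 5, downsample = 5) {
  stopifnot(inherits(raw, "stapaw_raw"), downsample >= 1)
  n <- length(raw$x)
  if (n <= downsample + 2 * downsample)
    stop("track ", raw$track_id, " too short to preprocess", call. = FALSE)
  if (n < smooth_window)
    stop("track ", raw$track_id, " shorter than the smoothing window",
         call. = FALSE)
  xs <- moving_average(raw$x, smooth_window)
  ys <- moving_average(raw$y, smooth_window)
  keep <- seq(1, n, by = downsample)
  xs <- xs[keep]; ys <- ys[keep]
  tt <- raw$t[keep]
  Ii <- if (!is.null(raw$I)) raw$I[keep] else NULL
  dx <- diff(xs); dy <- diff(ys)
  heading <- atan2(dy, dx)            # defined from sample 2 on
  dr <- sqrt(dx^2 + dy^2)
  dtheta <- wrap_angle(diff(heading)) # defined from sample 3 on
  # step i of the output corresponds to down-sampled sample i + 2
  idx <- seq(3, length(xs))
  new_track(track_id = raw$track_id,
            dt = downsample / raw$frame_rate,
            t = tt[idx], x = xs[idx], y = ys[idx],
            heading = heading[idx - 1],
            dtheta = dtheta[idx - 2],
            dr = dr[idx - 1],
            I = if (!is.null(Ii)) Ii[idx] else NULL)
}

#' Construct a kinematic track
#'
#' Low-level constructor for per-step series; [preprocess()] and the
#' simulator call this. All series must have equal length.
#'
#' @param track_id identifier.
#' @param dt seconds per step.
#' @param t,x,y step times (s) and positions (cm) at the end of each step.
#' @param heading heading (radians) over each step.
#' @param dtheta heading change per step, wrapped to (-pi, pi].
#' @param dr step displacement, cm, >= 0.
#' @param C,dCp,bearing optional sensory series (see [extract_sensory()]).
#' @param I optional stimulus series.
#' @return an object of class `stapaw_track`.
#' @export
new_track <- function(track_id, dt, t, x, y, heading, dtheta, dr,
                      C = NULL, dCp = NULL, bearing = NULL, I = NULL) {
  Tn <- length(dtheta)
  lens <- c(length(t), length(x), length(y), length(heading), length(dr))
  if (any(lens != Tn)) stop("track series length mismatch", call. = FALSE)
  if (any(dr < 0)) stop("negative step displacement", call. = FALSE)
  stopifnot(dt > 0)
  dtheta <- wrap_angle(dtheta)
  structure(list(track_id = track_id, dt = dt, t = t, x = x, y = y,
                 heading = heading, dtheta = dtheta, dr = dr,
                 C = C, dCp = dCp, bearing = bearing, I = I),
            class = "stapaw_track")
}

track_length <- function(track) length(track$dtheta)

#' @export
print.stapaw_track <- function(x, ...) {
  cat(sprintf("<stapaw track '%s': %d steps, dt = %.4f s%s>\n",
              as.character(x$track_id), track_length(x), x$dt,
              if (!is.null(x$C)) ", with sensory series" else ""))
  invisible(x)
}

#' Filter tracks by spatial extent and duration
#'
#' Removes tracks whose bounding-box area or recorded duration falls below
#' the thresholds (defaults: 1 cm^2 and 3 minutes).
#'
#' @param tracks list of `stapaw_track`.
#' @param min_area minimum bounding-box area, cm^2.
#' @param min_duration minimum duration, seconds.
#' @param quiet suppress the removal-count message.
#' @return a `stapaw_dataset` of the retained tracks, with attribute
#'   `n_removed`.
#' @export
filter_tracks <- function(tracks, min_area = 1, min_duration = 180,
                          quiet = FALSE) {
  keep <- vapply(tracks, function(tr) {
    area <- diff(range(tr$x)) * diff(range(tr$y))
    dur <- track_length(tr) * tr$dt
    area >= min_area && dur >= min_duration
  }, logical(1))
  n_removed <- sum(!keep)
  if (!quiet)
    message(sprintf("filter_tracks: removed %d of %d tracks",
                    n_removed, length(tracks)))
  if (!any(keep))
    stop("all tracks removed by filtering", call. = FALSE)
  ds <- stapaw_dataset(tracks[keep])
  attr(ds, "n_removed") <- n_removed
  ds
}

#' Bundle tracks into a dataset
#'
#' @param tracks nonempty list of `stapaw_track` sharing the same `dt`.
#' @param metadata optional named list of condition labels etc.
#' @return an object of class `stapaw_dataset`.
#' @export
stapaw_dataset <- function(tracks, metadata = list()) {
  stopifnot(length(tracks) >= 1)
  dts <- vapply(tracks, `[[`, numeric(1), "dt")
  if (diff(range(dts)) > 1e-9)
    stop("all tracks in a dataset must share dt", call. = FALSE)
  structure(list(tracks = tracks, dt = dts[1], metadata = metadata),
            class = "stapaw_dataset")
}

#' @export
print.stapaw_dataset <- function(x, ...) {
  cat(sprintf("<stapaw dataset: %d tracks, %d total steps, dt = %.4f s>\n",
              length(x$tracks),
              sum(vapply(x$tracks, track_length, integer(1))), x$dt))
  invisible(x)
}

dataset_steps <- function(dataset)
  sum(vapply(dataset$tracks, track_length, integer(1)))

#' Attach sensory series to a track
#'
#' Computes, at every step, the experienced concentration `C`, the
#' perpendicular concentration difference `dCp` (concentration at a point
#' `sensor_offset` cm to the left of the heading minus the point to the
#' right), and the bearing to the local gradient in degrees (0 =
#' upgradient, 180 = downgradient).
#'
#' @param track a `stapaw_track`.
#' @param env a `stapaw_env` covering the track's extent.
#' @param sensor_offset lateral sensor offset, cm (default 0.05).
#' @return the track with `C`, `dCp` and `bearing` filled in.
#' @export
extract_sensory <- function(track, env, sensor_offset = 0.05) {
  p <- cbind(track$x, track$y)
  C <- concentration(env, p)
  left <- p + sensor_offset * cbind(cos(track$heading + pi / 2),
                                    sin(track$heading + pi / 2))
  right <- p - sensor_offset * cbind(cos(track$heading + pi / 2),
                                     sin(track$heading + pi / 2))
  clamp <- function(q) t(apply(q, 1, function(r) reflect_position(env, r)))
  dCp <- concentration(env, clamp(left)) - concentration(env, clamp(right))
  g <- env_gradient(env, p)
  grad_angle <- atan2(g[, 2], g[, 1])
  b <- abs(wrap_angle(grad_angle - track$heading)) * 180 / pi
  gmag <- sqrt(rowSums(g^2))
  b[gmag < 1e-12] <- NA_real_
  track$C <- C
  track$dCp <- dCp
  track$bearing <- b
  track
}

#' Write a dataset of tracks to CSV
#'
#' Long format with columns `track_id, t, x, y, heading, dtheta, dr` plus
#' any sensory/latent series present.
#'
#' @param dataset a `stapaw_dataset` (or list of tracks).
#' @param path output file.
#' @return invisibly, the data frame written.
#' @export
write_tracks <- function(dataset, path) {
  tracks <- if (inherits(dataset, "stapaw_dataset")) dataset$tracks else dataset
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(track_id = tr$track_id, t = tr$t, x = tr$x, y = tr$y,
                     heading = tr$heading, dtheta = tr$dtheta, dr = tr$dr)
    for (f in c("C", "dCp", "bearing", "I", "z", "q"))
      if (!is.null(tr[[f]])) df[[f]] <- tr[[f]]
    df
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a processed track table
#'
#' Inverse of [write_tracks()]: reads a long-format CSV of per-step
#' kinematic series (`track_id, t, x, y, heading, dtheta, dr` plus any of
#' `C, dCp, bearing, I, z, q`) back into tracks.
#'
#' @param path CSV file written by [write_tracks()] (or of the same shape).
#' @param dt seconds per step; inferred from the time stamps when NULL.
#' @return a `stapaw_dataset`.
#' @export
read_track_table <- function(path, dt = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t", "x", "y", "heading", "dtheta", "dr")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("columns not found in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tracks <- lapply(unique(tab$track_id), function(id) {
    rows <- tab[tab$track_id == id, , drop = FALSE]
    rows <- rows[order(rows$t), , drop = FALSE]
    step <- dt %||% stats::median(diff(rows$t))
    tr <- new_track(track_id = id, dt = step, t = rows$t, x = rows$x,
                    y = rows$y, heading = rows$heading,
                    dtheta = rows$dtheta, dr = rows$dr,
                    C = rows$C, dCp = rows$dCp, bearing = rows$bearing,
                    I = rows$I)
    if (!is.null(rows$z)) tr$z <- as.integer(rows$z)
    if (!is.null(rows$q)) tr$q <- as.integer(rows$q)
    tr
  })
  stapaw_dataset(tracks)
}
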