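# YAML configuration: preprocessing and environment blocks shared by the
# command-line interface and analysis scripts.

#' Read a configuration file
#'
#' Expects optional `preprocessing` and `environment` blocks:
#' ```yaml
#' preprocessing:
#'   smooth_window: 5
#'   downsample: 5
#'   min_area_cm2: 1
#'   min_duration_s: 180
#'   sensor_offset_cm: 0.05
#' environment:
#'   kind: linear        # linear | gaussian | grid
#'   c0: 0
#'   slope: [5.56, 0]
#'   bounds: [0, 9, 0, 9]
#'   # gaussian: center, amplitude, sigma_cm, radius_cm
#' ```
#'
#' @param path YAML file.
#' @return list with `preprocessing` (defaults filled in) and `env`
#'   (a `stapaw_env`, or NULL if no environment block).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pp_defaults <- list(smooth_window = 5, downsample = 5, min_area_cm2 = 1,
                      min_duration_s = 180, sensor_offset_cm = 0.05)
  pp <- utils::modifyList(pp_defaults, cfg$preprocessing %||% list())
  env <- NULL
  if (!is.null(cfg$environment)) {
    e <- cfg$environment
    env <- switch(e$kind %||% "linear",
      linear = env_linear(c0 = e$c0 %||% 0,
                          slope = unlist(e$slope) %||% c(50 / 9, 0),
                          bounds = unlist(e$bounds) %||% c(0, 9, 0, 9)),
      gaussian = env_gaussian(center = unlist(e$center) %||% c(0, 0),
                              amplitude = e$amplitude %||% 1,
                              sigma = e$sigma_cm %||% 1.5,
                              radius = e$radius_cm %||% 4.5),
      stop("unknown environment kind: ", e$kind, call. = FALSE))
  }
  list(preprocessing = pp, env = env)
}

#' Preprocess a trajectory table end to end
#'
#' Convenience pipeline: read raw tracks, smooth/down-sample, apply the
#' inclusion rules, and attach sensory series from an environment.
#'
#' @param path CSV of raw centroid trajectories.
#' @param env a `stapaw_env` (or NULL to skip sensory extraction).
#' @param config list as returned by [read_config()]'s `preprocessing`
#'   element; missing entries take the defaults.
#' @param frame_rate sampling rate of the raw table, Hz.
#' @return a `stapaw_dataset`.
#' @export
load_dataset <- function(path, env = NULL, config = list(),
                         frame_rate = 14) {
  pp <- utils::modifyList(
    list(smooth_window = 5, downsample = 5, min_area_cm2 = 1,
         min_duration_s = 180, sensor_offset_cm = 0.05), config)
  raws <- read_tracks(path, frame_rate = frame_rate)
  tracks <- lapply(raws, preprocess, smooth_window = pp$smooth_window,
                   downsample = pp$downsample)
  ds <- filter_tracks(tracks, min_area = pp$min_area_cm2,
                      min_duration = pp$min_duration_s, quiet = TRUE)
  if (!is.null(env))
    ds$tracks <- lapply(ds$tracks, extract_sensory, env = env,
                        sensor_offset = pp$sensor_offset_cm)
  ds
}
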