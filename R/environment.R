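# Analytic concentration landscapes: linear gradients, Gaussian plumes, and
# sampled grids with bilinear interpolation. Used both for sensory feature
# extraction from recorded tracks and for closed-loop simulation.

#' Linear concentration gradient
#'
#' Field `c0 + slope[1] * x + slope[2] * y` on a rectangular domain. The
#' default reproduces a 0-50 mM gradient across a 9 cm square arena.
#'
#' @param c0 concentration at the origin (e.g. mM).
#' @param slope length-2 gradient vector (concentration per cm).
#' @param bounds domain as `c(xmin, xmax, ymin, ymax)` in cm.
#' @return an object of class `c("stapaw_env_linear", "stapaw_env")`.
#' @export
env_linear <- function(c0 = 0, slope = c(50 / 9, 0),
                       bounds = c(0, 9, 0, 9)) {
  stopifnot(length(slope) == 2, length(bounds) == 4,
            bounds[2] > bounds[1], bounds[4] > bounds[3])
  structure(list(kind = "linear", c0 = c0, slope = as.numeric(slope),
                 bounds = as.numeric(bounds)),
            class = c("stapaw_env_linear", "stapaw_env"))
}

#' Gaussian concentration plume
#'
#' Radially symmetric field `A * exp(-||x - center||^2 / (2 sigma^2))` on a
#' disk-shaped domain, the stand-in for a calibrated odor landscape.
#'
#' @param center source position, cm.
#' @param amplitude peak concentration A.
#' @param sigma spatial width, cm (> 0).
#' @param radius domain radius around the center, cm.
#' @return an object of class `c("stapaw_env_gaussian", "stapaw_env")`.
#' @export
env_gaussian <- function(center = c(0, 0), amplitude = 1, sigma = 1.5,
                         radius = 4.5) {
  stopifnot(sigma > 0, radius > 0, length(center) == 2)
  structure(list(kind = "gaussian", center = as.numeric(center),
                 amplitude = amplitude, sigma = sigma, radius = radius),
            class = c("stapaw_env_gaussian", "stapaw_env"))
}

#' Sampled concentration grid
#'
#' Concentration sampled on a regular grid, queried by bilinear
#' interpolation; gradients by central differences.
#'
#' @param x,y strictly increasing grid coordinates, cm.
#' @param values matrix of concentrations, `length(x)` rows and `length(y)`
#'   columns (`values[i, j]` at `(x[i], y[j])`).
#' @return an object of class `c("stapaw_env_grid", "stapaw_env")`.
#' @export
env_grid <- function(x, y, values) {
  stopifnot(all(diff(x) > 0), all(diff(y) > 0),
            nrow(values) == length(x), ncol(values) == length(y),
            all(is.finite(values)))
  structure(list(kind = "grid", x = as.numeric(x), y = as.numeric(y),
                 values = values,
                 bounds = c(min(x), max(x), min(y), max(y))),
            class = c("stapaw_env_grid", "stapaw_env"))
}

as_pos_matrix <- function(position) {
  if (is.matrix(position)) {
    stopifnot(ncol(position) == 2)
    position
  } else {
    stopifnot(length(position) == 2)
    matrix(position, ncol = 2)
  }
}

#' Test whether positions lie inside an environment's domain
#' @param env a `stapaw_env`.
#' @param position length-2 vector or n x 2 matrix of positions (cm).
#' @return logical vector.
#' @export
in_domain <- function(env, position) {
  p <- as_pos_matrix(position)
  if (inherits(env, "stapaw_env_gaussian")) {
    sqrt((p[, 1] - env$center[1])^2 + (p[, 2] - env$center[2])^2) <=
      env$radius + 1e-9
  } else {
    b <- env$bounds
    p[, 1] >= b[1] - 1e-9 & p[, 1] <= b[2] + 1e-9 &
      p[, 2] >= b[3] - 1e-9 & p[, 2] <= b[4] + 1e-9
  }
}

check_domain <- function(env, p) {
  if (!all(in_domain(env, p)))
    stop("position outside the environment domain", call. = FALSE)
}

#' Concentration at a position
#' @param env a `stapaw_env`.
#' @param position length-2 vector or n x 2 matrix (cm).
#' @return concentration value(s).
#' @export
concentration <- function(env, position) UseMethod("concentration")

#' @export
concentration.stapaw_env_linear <- function(env, position) {
  p <- as_pos_matrix(position)
  check_domain(env, p)
  env$c0 + p[, 1] * env$slope[1] + p[, 2] * env$slope[2]
}

#' @export
concentration.stapaw_env_gaussian <- function(env, position) {
  p <- as_pos_matrix(position)
  check_domain(env, p)
  d2 <- (p[, 1] - env$center[1])^2 + (p[, 2] - env$center[2])^2
  env$amplitude * exp(-d2 / (2 * env$sigma^2))
}

#' @export
concentration.stapaw_env_grid <- function(env, position) {
  p <- as_pos_matrix(position)
  check_domain(env, p)
  vapply(seq_len(nrow(p)), function(i) {
    grid_bilinear(env, p[i, 1], p[i, 2])
  }, numeric(1))
}

grid_bilinear <- function(env, px, py) {
  ix <- findInterval(px, env$x, rightmost.closed = TRUE)
  iy <- findInterval(py, env$y, rightmost.closed = TRUE)
  ix <- max(1, min(ix, length(env$x) - 1))
  iy <- max(1, min(iy, length(env$y) - 1))
  tx <- (px - env$x[ix]) / (env$x[ix + 1] - env$x[ix])
  ty <- (py - env$y[iy]) / (env$y[iy + 1] - env$y[iy])
  v <- env$values
  (1 - tx) * (1 - ty) * v[ix, iy] + tx * (1 - ty) * v[ix + 1, iy] +
    (1 - tx) * ty * v[ix, iy + 1] + tx * ty * v[ix + 1, iy + 1]
}

#' Concentration gradient at a position
#'
#' Analytic for linear and Gaussian fields, central differences for grids.
#'
#' @param env a `stapaw_env`.
#' @param position length-2 vector or n x 2 matrix (cm).
#' @return n x 2 matrix of gradient vectors (concentration per cm).
#' @export
env_gradient <- function(env, position) UseMethod("env_gradient")

#' @export
env_gradient.stapaw_env_linear <- function(env, position) {
  p <- as_pos_matrix(position)
  check_domain(env, p)
  matrix(env$slope, nrow = nrow(p), ncol = 2, byrow = TRUE)
}

#' @export
env_gradient.stapaw_env_gaussian <- function(env, position) {
  p <- as_pos_matrix(position)
  check_domain(env, p)
  c0 <- concentration(env, p)
  cbind(-(p[, 1] - env$center[1]) / env$sigma^2 * c0,
        -(p[, 2] - env$center[2]) / env$sigma^2 * c0)
}

#' @export
env_gradient.stapaw_env_grid <- function(env, position) {
  p <- as_pos_matrix(position)
  check_domain(env, p)
  hx <- min(diff(env$x))
  hy <- min(diff(env$y))
  t(apply(p, 1, function(q) {
    xl <- max(q[1] - hx, env$bounds[1]); xr <- min(q[1] + hx, env$bounds[2])
    yl <- max(q[2] - hy, env$bounds[3]); yr <- min(q[2] + hy, env$bounds[4])
    c((grid_bilinear(env, xr, q[2]) - grid_bilinear(env, xl, q[2])) / (xr - xl),
      (grid_bilinear(env, q[1], yr) - grid_bilinear(env, q[1], yl)) / (yr - yl))
  }))
}

#' Widen a Gaussian plume
#'
#' Returns the same plume with its spatial width scaled by `factor`; used to
#' build shallower-gradient generalization environments.
#'
#' @param env a Gaussian `stapaw_env`.
#' @param factor positive scale on sigma (e.g. 1.7).
#' @return a new Gaussian environment.
#' @export
widen <- function(env, factor) {
  if (!inherits(env, "stapaw_env_gaussian"))
    stop("widen() is defined for Gaussian environments only", call. = FALSE)
  stopifnot(factor > 0)
  env_gaussian(center = env$center, amplitude = env$amplitude,
               sigma = env$sigma * factor, radius = env$radius)
}

# Reflect a proposed position back into the domain (closed-loop simulation
# boundary rule). Returns the corrected position.
reflect_position <- function(env, pos) {
  if (inherits(env, "stapaw_env_gaussian")) {
    d <- pos - env$center
    r <- sqrt(sum(d^2))
    if (r > env$radius) {
      pos <- env$center + d / r * (2 * env$radius - r) * 1.0
      # fold back if still outside (very large step)
      d <- pos - env$center; r <- sqrt(sum(d^2))
      if (r > env$radius) pos <- env$center + d / r * env$radius * 0.999
    }
    pos
  } else {
    b <- env$bounds
    for (k in 1:2) {
      lo <- b[2 * k - 1]; hi <- b[2 * k]
      span <- hi - lo
      v <- pos[k]
      if (v < lo || v > hi) {
        v <- (v - lo) %% (2 * span)
        v <- ifelse(v > span, 2 * span - v, v)
        pos[k] <- lo + v
      }
    }
    pos
  }
}

#' @export
print.stapaw_env <- function(x, ...) {
  cat("<stapaw environment:", x$kind, "field>\n")
  invisible(x)
}
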