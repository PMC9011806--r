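#' MT stage configuration
#'
#' Describes the grid of MT macrocolumns: at every pixel of the flow grid
#' there is one macrocolumn of `n_directions * n_speeds` units (168 at the
#' defaults of 24 directions spaced 15 degrees apart and 7 speeds) with
#' joint direction and speed tuning. Each unit's response is the product of
#' a von Mises direction tuning curve (concentration `kappa`) evaluated at
#' the local flow direction and a Gaussian speed tuning curve evaluated at
#' the local flow magnitude; each (direction, speed) channel is then pooled
#' spatially with a Gaussian kernel of `pooling_sigma` grid units truncated
#' at 4 sigma (9-pixel support at the default), the unit's receptive field.
#'
#' @param grid Flow/MT grid resolution (pixels per side). Default 256.
#' @param n_directions Number of preferred directions. Default 24.
#' @param n_speeds Number of preferred speeds. Default 7.
#' @param pooling_sigma Receptive-field Gaussian sigma (grid units).
#'   Default 1.0.
#' @param kappa von Mises direction-tuning concentration. Default 10
#'   (half-height full width around 43 degrees, a free parameter of the
#'   model).
#' @param fov_deg Field of view (degrees). Default 90.
#' @param cutoff_sigma Speed-response clip radius in sigma units.
#'   Default 4.
#' @return An object of class `mt_config`.
#' @export
mt_config <- function(grid = 256L, n_directions = 24L, n_speeds = 7L,
                      pooling_sigma = 1.0, kappa = 10, fov_deg = 90,
                      cutoff_sigma = 4) {
  cfg <- list(grid = as.integer(grid), n_directions = as.integer(n_directions),
              n_speeds = as.integer(n_speeds), pooling_sigma = pooling_sigma,
              kappa = kappa, fov_deg = fov_deg, cutoff_sigma = cutoff_sigma)
  if (cfg$grid < 2L || cfg$n_directions < 2L || cfg$n_speeds < 1L)
    stop("invalid MT configuration")
  structure(cfg, class = "mt_config")
}

#' Macrocolumn size of an MT configuration
#'
#' @param config An [mt_config()].
#' @return `n_directions * n_speeds`.
#' @export
macrocolumn_size <- function(config) {
  stopifnot(inherits(config, "mt_config"))
  config$n_directions * config$n_speeds
}

#' MT receptive-field angular diameter
#'
#' Diameter, in degrees of visual angle, of the pooling kernel's support
#' (`2 * ceiling(4 sigma) + 1` pixels) under the configuration's
#' degrees-per-pixel factor.
#'
#' @param config An [mt_config()].
#' @return Angular diameter in degrees.
#' @export
mt_rf_diameter_deg <- function(config) {
  stopifnot(inherits(config, "mt_config"))
  support <- 2L * ceiling(4 * config$pooling_sigma) + 1L
  support * config$fov_deg / config$grid
}

# Preferred directions (radians), evenly spaced on the circle.
mt_preferred_directions <- function(config) {
  (seq_len(config$n_directions) - 1L) * 2 * pi / config$n_directions
}

# Banded pooling matrix: Gaussian kernel truncated at 4 sigma, normalized
# to sum 1; zero padding at the borders. Cached per (grid, sigma).
pooling_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(grid, sigma) {
    key <- sprintf("%d_%g", grid, sigma)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- ceiling(4 * sigma)
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    km <- matrix(0, grid, grid)
    for (o in -r:r) {
      idx <- seq_len(grid)
      j <- idx + o
      ok <- j >= 1L & j <= grid
      km[cbind(idx[ok], j[ok])] <- k[o + r + 1L]
    }
    cache[[key]] <- km
    km
  }
})

# von Mises direction tuning (peak 1) of flow directions `theta` (radians)
# against every preferred direction: returns length(theta) x D matrix.
direction_tuning <- function(theta, config) {
  prefs <- mt_preferred_directions(config)
  vapply(prefs,
         function(p) exp(config$kappa * (cos(theta - p) - 1)),
         numeric(length(theta)))
}

#' MT population response to a flow field
#'
#' Per-pixel responses are the product of direction tuning (von Mises, of
#' the local flow direction against each preferred direction) and speed
#' tuning (Gaussian, of the local flow magnitude against each curve of the
#' supplied tuning set); invalid and zero-flow pixels contribute nothing.
#' Each of the `n_directions * n_speeds` channels is then smoothed with the
#' Gaussian pooling kernel.
#'
#' @param flow A [flow_field()] on the configuration's grid.
#' @param tuning A `tuning_curve_set` with `n_speeds` curves.
#' @param config An [mt_config()].
#' @return An object of class `mt_response`: list with `activity` (a
#'   `grid x grid x n_directions x n_speeds` array in `[0, 1]`), `tuning`
#'   and `config`.
#' @export
mt_respond <- function(flow, tuning, config) {
  stopifnot(inherits(flow, "flow_field"), inherits(config, "mt_config"))
  check_mt_inputs(flow, tuning, config)
  g <- config$grid
  parts <- mt_pixel_tuning(flow, tuning, config)
  km <- pooling_matrix(g, config$pooling_sigma)
  act <- array(0, c(g, g, config$n_directions, config$n_speeds))
  for (d in seq_len(config$n_directions)) {
    for (s in seq_len(config$n_speeds)) {
      ch <- matrix(parts$dir[, d] * parts$spd[, s], g, g)
      act[, , d, s] <- km %*% ch %*% t(km)
    }
  }
  structure(list(activity = act, tuning = tuning, config = config),
            class = "mt_response")
}

check_mt_inputs <- function(flow, tuning, config) {
  if (nrow(flow$u) != config$grid || ncol(flow$u) != config$grid)
    stop(sprintf("flow grid %dx%d does not match MT grid %d",
                 nrow(flow$u), ncol(flow$u), config$grid))
  if (!inherits(tuning, "tuning_curve_set"))
    stop("tuning must be a tuning_curve_set")
  if (tuning$n_neurons != config$n_speeds)
    stop(sprintf("tuning has %d curves but MT expects %d speeds",
                 tuning$n_neurons, config$n_speeds))
  invisible(TRUE)
}

# Unpooled per-pixel tuning factors: direction matrix (P x D) and speed
# matrix (P x S), with invalid / zero-magnitude pixels zeroed.
mt_pixel_tuning <- function(flow, tuning, config) {
  m <- as.vector(flow_speed(flow))
  theta <- atan2(as.vector(flow$v), as.vector(flow$u))
  live <- as.vector(flow$valid) & m > 0
  dir <- direction_tuning(theta, config)
  dir[!live, ] <- 0
  spd <- tuning_response(m, tuning, config$cutoff_sigma)
  spd <- matrix(spd, nrow = length(m))
  spd[!live, ] <- 0
  list(dir = dir, spd = spd, live = live)
}

#' Pooled direction-marginal MT signal
#'
#' The MSTd template match sums MT activity over speed channels, and
#' spatial pooling is linear, so the quantity the downstream stage needs is
#' the pooled sum over speeds: a `grid^2 x n_directions` matrix. Computing
#' it directly (one pooling pass per direction instead of one per
#' direction-speed pair) is the per-frame hot path of the pipeline; it
#' equals `apply(mt_respond(...)$activity, c(1, 2, 3), sum)` up to floating
#' error.
#'
#' @inheritParams mt_respond
#' @return A `grid^2 x n_directions` matrix (pixels in column-major order).
#' @export
mt_direction_signal <- function(flow, tuning, config) {
  stopifnot(inherits(flow, "flow_field"), inherits(config, "mt_config"))
  check_mt_inputs(flow, tuning, config)
  g <- config$grid
  parts <- mt_pixel_tuning(flow, tuning, config)
  stot <- rowSums(parts$spd)
  km <- pooling_matrix(g, config$pooling_sigma)
  out <- matrix(0, g * g, config$n_directions)
  for (d in seq_len(config$n_directions)) {
    ch <- matrix(parts$dir[, d] * stot, g, g)
    out[, d] <- as.vector(km %*% ch %*% t(km))
  }
  out
}

#' MT population with re-tunable speed curves
#'
#' Bundles an [mt_config()] with the current speed tuning set; [retune()]
#' swaps in a new set (e.g. each frame under dynamic encoding). Speed
#' channel indices always denote rank order, slowest to fastest — never an
#' absolute speed.
#'
#' @param config An [mt_config()].
#' @param tuning A `tuning_curve_set` with `n_speeds` curves.
#' @return An object of class `mt_population`.
#' @export
mt_population <- function(config, tuning) {
  stopifnot(inherits(config, "mt_config"))
  check_tuning_size(tuning, config)
  structure(list(config = config, tuning = tuning), class = "mt_population")
}

check_tuning_size <- function(tuning, config) {
  if (!inherits(tuning, "tuning_curve_set"))
    stop("tuning must be a tuning_curve_set")
  if (tuning$n_neurons != config$n_speeds)
    stop(sprintf("tuning has %d curves but MT expects %d speeds",
                 tuning$n_neurons, config$n_speeds))
  if (is.unsorted(tuning$curves$mu))
    stop("tuning peaks must be non-decreasing in rank")
  invisible(TRUE)
}

#' Replace the speed tuning of an MT population
#'
#' @param population An [mt_population()].
#' @param new_tuning A `tuning_curve_set` with `n_speeds` curves.
#' @return The population with the new tuning installed.
#' @export
retune <- function(population, new_tuning) {
  stopifnot(inherits(population, "mt_population"))
  check_tuning_size(new_tuning, population$config)
  population$tuning <- new_tuning
  population
}

#' Response of an MT population to a flow field
#'
#' Convenience wrapper around [mt_respond()] using the population's current
#' tuning.
#'
#' @param population An [mt_population()].
#' @param flow A [flow_field()].
#' @return An `mt_response`.
#' @export
respond <- function(population, flow) {
  stopifnot(inherits(population, "mt_population"))
  mt_respond(flow, population$tuning, population$config)
}
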