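#' Empirical distribution of optic-flow speeds
#'
#' A `speed_distribution` is a histogram of optic-flow vector magnitudes
#' (degrees/frame) with a piecewise-linear interpolated CDF. It is the
#' empirical estimate of the stimulus probability distribution p(s) from
#' which efficient tuning curves are derived.
#'
#' The histogram spans `[0, max(observed speed)]` by construction when built
#' with [build_speed_distribution()]. A stream in which every observed speed
#' is identical (e.g. all-zero flow) collapses to a point mass: `bin_edges`
#' has two equal entries and the distribution is flagged degenerate; tuning
#' derived from it collapses too (see [derive_tuning()]).
#'
#' @param bin_edges Numeric vector of bin edges, non-negative and strictly
#'   increasing (equal edges only for the point-mass case).
#' @param bin_mass Per-bin probability mass; non-negative, sums to 1.
#' @param n_samples Number of flow vectors that contributed to the histogram.
#' @return An object of class `speed_distribution` with fields `bin_edges`,
#'   `bin_mass`, `n_samples` and `point_mass`.
#' @seealso [build_speed_distribution()], [derive_tuning()]
#' @export
speed_distribution <- function(bin_edges, bin_mass, n_samples) {
  bin_edges <- as.numeric(bin_edges)
  bin_mass <- as.numeric(bin_mass)
  if (length(bin_edges) < 2L)
    stop("bin_edges must have at least two entries")
  if (any(bin_edges < 0))
    stop("speeds are non-negative; bin_edges must be >= 0")
  point_mass <- length(bin_edges) == 2L && bin_edges[1] == bin_edges[2]
  if (!point_mass && any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  if (length(bin_mass) != length(bin_edges) - 1L)
    stop("bin_mass must have one entry per bin")
  if (any(bin_mass < 0))
    stop("bin_mass entries must be non-negative")
  if (abs(sum(bin_mass) - 1) > 1e-9)
    stop("bin_mass must sum to 1")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be >= 1")
  structure(
    list(bin_edges = bin_edges, bin_mass = bin_mass,
         n_samples = n_samples, point_mass = point_mass),
    class = "speed_distribution"
  )
}

#' Pool flow-field magnitudes into a speed distribution
#'
#' Pools the magnitudes of every valid flow vector across all supplied
#' fields and frames, equally weighted, into a histogram spanning
#' `[0, max observed speed]`. This is the distribution "seen" by the
#' encoding stage over whatever window of frames the caller supplies.
#'
#' @param flow_fields A single [flow_field()], a list of them, or a numeric
#'   vector of magnitudes (degrees/frame).
#' @param bins Number of histogram bins (>= 2). Default 128.
#' @return A [speed_distribution()].
#' @export
build_speed_distribution <- function(flow_fields, bins = 128L) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("bins must be >= 2")
  mags <- pool_flow_magnitudes(flow_fields)
  if (length(mags) == 0L) stop("no flow data")
  speed_histogram(mags, bins)
}

# Gather magnitudes of valid vectors from flow field(s) or accept raw speeds.
pool_flow_magnitudes <- function(flow_fields) {
  if (is.numeric(flow_fields)) {
    mags <- as.numeric(flow_fields)
    if (any(mags < 0)) stop("speeds must be non-negative")
    return(mags[is.finite(mags)])
  }
  if (inherits(flow_fields, "flow_field")) flow_fields <- list(flow_fields)
  if (!is.list(flow_fields) || length(flow_fields) == 0L) stop("no flow data")
  mags <- lapply(flow_fields, function(f) {
    if (!inherits(f, "flow_field")) stop("inputs must be flow_field objects")
    m <- sqrt(f$u^2 + f$v^2)
    m[f$valid & is.finite(m)]
  })
  unlist(mags, use.names = FALSE)
}

# Histogram of speeds on [0, max]; point-mass short-circuit when all speeds
# coincide (zero-width support).
speed_histogram <- function(mags, bins) {
  n <- length(mags)
  if (n == 0L) stop("no flow data")
  hi <- max(mags)
  if (hi - min(mags) < .Machine$double.eps * max(1, hi)) {
    return(speed_distribution(c(hi, hi), 1, n))
  }
  edges <- seq(0, hi, length.out = bins + 1L)
  idx <- findInterval(mags, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  speed_distribution(edges, counts / n, n)
}

#' Uniform reference speed distribution
#'
#' Analytic uniform distribution of speeds on `[0, max_speed]`, used for the
#' static-uniform tuning baseline (default range 0 to 5.3 degrees/frame).
#'
#' @param max_speed Upper end of the uniform range (degrees/frame).
#' @param bins Number of bins. Default 128.
#' @return A [speed_distribution()] with equal mass in every bin.
#' @export
uniform_speed_distribution <- function(max_speed, bins = 128L) {
  if (max_speed <= 0) stop("max_speed must be positive")
  bins <- as.integer(bins)
  speed_distribution(seq(0, max_speed, length.out = bins + 1L),
                     rep(1 / bins, bins), n_samples = bins)
}

#' @export
print.speed_distribution <- function(x, ...) {
  if (x$point_mass) {
    cat(sprintf("speed_distribution: point mass at %.4g deg/frame (n = %d)\n",
                x$bin_edges[1], x$n_samples))
  } else {
    cat(sprintf(
      "speed_distribution: %d bins on [%.4g, %.4g] deg/frame (n = %d)\n",
      length(x$bin_mass), x$bin_edges[1], max(x$bin_edges), x$n_samples))
  }
  invisible(x)
}

#' Interpolated CDF of a speed distribution
#'
#' The CDF is piecewise linear within bins, so quantiles vary continuously
#' with the data instead of jumping between bin edges frame-to-frame.
#'
#' @param dist A [speed_distribution()].
#' @param s Speeds at which to evaluate (degrees/frame).
#' @return CDF values in `[0, 1]`.
#' @export
sd_cdf <- function(dist, s) {
  stopifnot(inherits(dist, "speed_distribution"))
  if (dist$point_mass) return(as.numeric(s >= dist$bin_edges[1]))
  cum <- c(0, cumsum(dist$bin_mass))
  cum[length(cum)] <- 1  # guard cumulative rounding
  stats::approx(dist$bin_edges, cum, xout = s, rule = 2, ties = "ordered")$y
}

#' Interpolated quantile function of a speed distribution
#'
#' Generalized inverse of the piecewise-linear CDF. Flat stretches of the
#' CDF (empty bins) resolve to the left-most speed attaining the level.
#'
#' @param dist A [speed_distribution()].
#' @param p Probability levels in `[0, 1]`.
#' @return Speeds (degrees/frame).
#' @export
sd_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "speed_distribution"))
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop("levels must lie in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  if (dist$point_mass) return(rep(dist$bin_edges[1], length(p)))
  cum <- c(0, cumsum(dist$bin_mass))
  cum[length(cum)] <- 1
  # generalized inverse: first edge index with cum >= p, interpolate inside bin
  vapply(p, function(pp) {
    j <- which(cum >= pp - 1e-15)[1]
    if (j == 1L) return(dist$bin_edges[1])
    lo <- cum[j - 1L]; hi <- cum[j]
    if (hi - lo <= 0) return(dist$bin_edges[j - 1L])
    w <- (pp - lo) / (hi - lo)
    dist$bin_edges[j - 1L] + w * (dist$bin_edges[j] - dist$bin_edges[j - 1L])
  }, numeric(1))
}

#' Interpolated probability density of a speed distribution
#'
#' Per-bin densities (mass / width) are linearly interpolated between bin
#' centers and clamped beyond the outermost centers.
#'
#' @param dist A [speed_distribution()].
#' @param s Speeds at which to evaluate.
#' @return Density values (1 / (degrees/frame)).
#' @export
sd_density <- function(dist, s) {
  stopifnot(inherits(dist, "speed_distribution"))
  if (dist$point_mass) stop("density undefined for a point-mass distribution")
  widths <- diff(dist$bin_edges)
  dens <- dist$bin_mass / widths
  centers <- dist$bin_edges[-length(dist$bin_edges)] + widths / 2
  if (length(centers) == 1L) return(rep(dens, length(s)))
  stats::approx(centers, dens, xout = s, rule = 2, ties = "ordered")$y
}

#' Neural density model d(s) = N p(s)
#'
#' Scales the stimulus density by the population size N so that the integral
#' of d(s) over the support equals N; its CDF, D(s), is evaluated at integer
#' levels to place tuning-curve peaks.
#'
#' @param dist A [speed_distribution()].
#' @param n_neurons Population size N (>= 1).
#' @return An object of class `density_model` with functions `d(s)` and
#'   `D(s)` plus fields `n_neurons` and `source`.
#' @export
density_model <- function(dist, n_neurons) {
  stopifnot(inherits(dist, "speed_distribution"))
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons < 1L) stop("n_neurons must be >= 1")
  structure(
    list(
      n_neurons = n_neurons,
      source = dist,
      d = function(s) n_neurons * sd_density(dist, s),
      D = function(s) n_neurons * sd_cdf(dist, s)
    ),
    class = "density_model"
  )
}

#' Integral of a density model over its support
#'
#' Computed from the underlying histogram mass, so it equals N exactly up to
#' floating error; exposed for validation.
#'
#' @param model A [density_model()].
#' @return The integral of d(s).
#' @export
density_integral <- function(model) {
  stopifnot(inherits(model, "density_model"))
  model$n_neurons * sum(model$source$bin_mass)
}

#' Serialize a speed distribution to JSON
#'
#' @param dist A [speed_distribution()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
speed_distribution_json <- function(dist, path = NULL) {
  stopifnot(inherits(dist, "speed_distribution"))
  x <- list(bin_edges = dist$bin_edges, bin_mass = dist$bin_mass,
            n_samples = dist$n_samples, point_mass = dist$point_mass)
  json <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a speed distribution from JSON
#'
#' @param path File path or JSON string produced by
#'   [speed_distribution_json()].
#' @return A [speed_distribution()].
#' @export
read_speed_distribution <- function(path) {
  x <- jsonlite::fromJSON(path)
  speed_distribution(x$bin_edges, x$bin_mass, x$n_samples)
}
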