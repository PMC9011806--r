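#' Derive efficient Gaussian speed-tuning curves from a stimulus distribution
#'
#' Implements efficient sensory encoding of a one-dimensional stimulus
#' (optic-flow speed) by a population of N Gaussian tuning curves. Writing
#' p(s) for the stimulus density and d(s) = N p(s) for the neural density,
#' the n-th peak is placed where the cumulative neural density D reaches
#' level n (so peaks sit at equal-probability-mass quantiles), the full
#' width at half maximum is the reciprocal of the local neural density,
#' FWHM_n = 1 / d(mu_n), and the Gaussian bandwidth follows as
#' sigma_n = FWHM_n / 2.355. Dense stimulus regions therefore receive many
#' narrow curves and sparse regions few broad ones, with each curve
#' capturing approximately 1/N of the stimulus probability mass.
#'
#' Peak placement evaluates the generalized inverse of the piecewise-linear
#' histogram CDF at levels n/N (`literal_eq2`, the default, placing the last
#' peak at the distribution maximum) or (n - 1/2)/N (`half_offset`, the
#' centered-quantile variant common in the efficient-coding literature).
#'
#' A point-mass distribution (all observed speeds identical, e.g. a single
#' frame of near-uniform flow) collapses every curve onto the same peak with
#' zero width; such curves carry `degenerate = TRUE` and, unless a bandwidth
#' floor is supplied, respond only to exactly the collapsed speed —
#' reproducing the erratic limit behaviour of a one-frame horizon. Passing
#' `sigma_floor` (degrees/frame) clips every bandwidth from below and
#' stabilizes the limit.
#'
#' @param dist A [speed_distribution()].
#' @param n_neurons Population size N (>= 1).
#' @param placement `"literal_eq2"` (default) or `"half_offset"`.
#' @param sigma_floor Optional lower bound on sigma (degrees/frame);
#'   `NULL` (default) leaves collapsed curves degenerate.
#' @param provenance Label recording how the source distribution was
#'   obtained: `"static_uniform"`, `"static_aggregate"` or `"dynamic"`.
#' @param horizon_frames Rolling-horizon length, recorded when
#'   `provenance = "dynamic"`.
#' @return An object of class `tuning_curve_set`: a list with `curves` (a
#'   data frame with columns `index`, `mu`, `fwhm`, `sigma`, `degenerate`),
#'   `n_neurons`, `placement`, `provenance`, `horizon_frames` and `source`.
#' @examples
#' u <- uniform_speed_distribution(50)
#' derive_tuning(u, 7)  # peaks at 50 n / 7, all sigma ~ 3.03
#' @export
derive_tuning <- function(dist, n_neurons,
                          placement = c("literal_eq2", "half_offset"),
                          sigma_floor = NULL,
                          provenance = c("dynamic", "static_uniform",
                                         "static_aggregate"),
                          horizon_frames = NULL) {
  stopifnot(inherits(dist, "speed_distribution"))
  placement <- match.arg(placement)
  provenance <- match.arg(provenance)
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons < 1L) stop("n_neurons must be >= 1")
  n <- seq_len(n_neurons)
  levels <- if (placement == "literal_eq2") n / n_neurons
            else (n - 0.5) / n_neurons

  if (dist$point_mass) {
    mu <- rep(dist$bin_edges[1], n_neurons)
    sigma <- rep(0, n_neurons)
    degenerate <- rep(TRUE, n_neurons)
  } else {
    mu <- sd_quantile(dist, levels)
    dens <- n_neurons * sd_density(dist, mu)  # d(mu) = N p(mu)
    sigma <- 1 / (2.355 * dens)
    degenerate <- rep(FALSE, n_neurons)
  }
  if (!is.null(sigma_floor)) {
    if (sigma_floor <= 0) stop("sigma_floor must be positive")
    sigma <- pmax(sigma, sigma_floor)
  }
  curves <- data.frame(index = n, mu = mu, fwhm = 2.355 * sigma,
                       sigma = sigma, degenerate = degenerate)
  structure(
    list(curves = curves, n_neurons = n_neurons, placement = placement,
         provenance = provenance, horizon_frames = horizon_frames,
         source = dist),
    class = "tuning_curve_set"
  )
}

#' @export
print.tuning_curve_set <- function(x, ...) {
  lab <- x$provenance
  if (identical(lab, "dynamic") && !is.null(x$horizon_frames))
    lab <- sprintf("dynamic, horizon %d", x$horizon_frames)
  cat(sprintf("tuning_curve_set: %d Gaussian speed curves (%s, %s)\n",
              x$n_neurons, lab, x$placement))
  print(x$curves, row.names = FALSE)
  invisible(x)
}

#' Response of one Gaussian speed cell
#'
#' Gaussian activation `exp(-(speed - mu)^2 / (2 sigma^2))`, hard-clipped to
#' zero beyond `mu +/- cutoff * sigma` so that responses drop to zero for
#' speeds outside the cell's sensitive range. A degenerate (collapsed)
#' curve responds 1 at exactly its peak speed and 0 elsewhere.
#'
#' @param speed Non-negative speeds (degrees/frame); vectorized.
#' @param curve One row of a tuning set's `curves` data frame (or any list
#'   with `mu`, `sigma`, `degenerate`).
#' @param cutoff Clip radius in units of sigma. Default 4 (keeps more than
#'   99.99% of the Gaussian mass).
#' @return Activations in `[0, 1]`.
#' @export
speed_response <- function(speed, curve, cutoff = 4) {
  if (any(speed < 0)) stop("speed must be non-negative")
  mu <- curve$mu; sigma <- curve$sigma
  if (isTRUE(curve$degenerate[1]) && sigma <= 0) {
    return(as.numeric(abs(speed - mu) < .Machine$double.eps * max(1, mu)))
  }
  z <- (speed - mu) / sigma
  r <- exp(-z^2 / 2)
  r[abs(z) > cutoff] <- 0
  r
}

#' Responses of a whole tuning set
#'
#' Evaluates [speed_response()] for every curve in the set.
#'
#' @param speed Non-negative speeds; vectorized.
#' @param tuning A `tuning_curve_set`.
#' @param cutoff Clip radius in sigma units (default 4).
#' @return A `length(speed) x N` matrix of activations.
#' @export
tuning_response <- function(speed, tuning, cutoff = 4) {
  stopifnot(inherits(tuning, "tuning_curve_set"))
  vapply(seq_len(tuning$n_neurons),
         function(i) speed_response(speed, tuning$curves[i, ], cutoff),
         numeric(length(speed)))
}

#' Serialize a tuning-curve set to JSON
#'
#' Records mu/fwhm/sigma per curve together with placement and provenance,
#' for audit and replay.
#'
#' @param tuning A `tuning_curve_set`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
tuning_json <- function(tuning, path = NULL) {
  stopifnot(inherits(tuning, "tuning_curve_set"))
  x <- list(
    n_neurons = tuning$n_neurons,
    placement = tuning$placement,
    provenance = tuning$provenance,
    horizon_frames = tuning$horizon_frames,
    curves = tuning$curves
  )
  json <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE,
                           dataframe = "columns")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a tuning-curve set from JSON
#'
#' @param path File path or JSON string produced by [tuning_json()].
#' @return A `tuning_curve_set` (without the source distribution).
#' @export
read_tuning <- function(path) {
  x <- jsonlite::fromJSON(path)
  curves <- as.data.frame(x$curves)
  structure(
    list(curves = curves, n_neurons = x$n_neurons, placement = x$placement,
         provenance = x$provenance, horizon_frames = x$horizon_frames,
         source = NULL),
    class = "tuning_curve_set"
  )
}
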