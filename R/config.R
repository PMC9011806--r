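#' Resolved run configuration
#'
#' Collects every tunable of the pipeline with its default, so a run can
#' be specified, serialized alongside its outputs, and replayed. Values
#' are validated against their documented ranges.
#'
#' @param ... Overrides of the defaults, using the dotted names shown by
#'   [default_run_config()] (e.g. `mt.grid = 64`,
#'   `dynamics.lambda = 0.5`).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Default run configuration values
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    mt.grid = 256L, mt.n_directions = 24L, mt.n_speeds = 7L,
    mt.pooling_sigma = 1.0, mt.kappa = 10,
    mstd.grid = 64L, fov_deg = 90,
    horizon.frames = 10L, static_uniform.max = 5.3,
    dynamics.lambda = 0.05, dynamics.inhibition = 1,
    noise.sigma = 0, noise.sky_outlier_rate = 0.02,
    bins = 128L, fps = 30,
    trials = 10L, seed = 1L,
    scene.kind = "cluttered"
  )
}

validate_run_config <- function(cfg) {
  if (cfg$dynamics.lambda <= 0 || cfg$dynamics.lambda > 1)
    stop("dynamics.lambda must lie in (0, 1]")
  if (cfg$horizon.frames < 1) stop("horizon.frames must be >= 1")
  if (cfg$static_uniform.max <= 0)
    stop("static_uniform.max must be positive")
  if (cfg$noise.sigma < 0) stop("noise.sigma must be non-negative")
  if (!cfg$scene.kind %in% c("ground_plane", "frontoparallel_wall",
                             "cluttered"))
    stop("unknown scene.kind")
  invisible(cfg)
}

#' Write a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to the defaults; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  ints <- c("mt.grid", "mt.n_directions", "mt.n_speeds", "mstd.grid",
            "horizon.frames", "bins", "trials", "seed")
  for (k in intersect(ints, names(vals))) vals[[k]] <- as.integer(vals[[k]])
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
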