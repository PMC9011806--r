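#' Absolute heading error between an estimate and ground truth
#'
#' Both headings are (azimuth, elevation) pairs in degrees of image-plane
#' angle. The total error is the angle between the two 3-D gaze unit
#' vectors `(tan az, tan el, 1) / norm`; per-axis errors are the absolute
#' azimuth and elevation differences.
#'
#' @param estimate A [decode_heading()] result or `c(azimuth, elevation)`
#'   in degrees.
#' @param truth Ground-truth `c(azimuth, elevation)` in degrees.
#' @return List with `total`, `azimuth`, `elevation` (degrees).
#' @export
heading_error <- function(estimate, truth) {
  if (inherits(estimate, "heading_estimate"))
    estimate <- c(estimate$azimuth, estimate$elevation)
  estimate <- as.numeric(estimate); truth <- as.numeric(truth)
  v1 <- gaze_vector(estimate); v2 <- gaze_vector(truth)
  total <- acos(pmin(pmax(sum(v1 * v2), -1), 1)) * 180 / pi
  list(total = total,
       azimuth = abs(estimate[1] - truth[1]),
       elevation = abs(estimate[2] - truth[2]))
}

gaze_vector <- function(azel) {
  v <- c(tan(azel[1] * pi / 180), tan(azel[2] * pi / 180), 1)
  v / sqrt(sum(v^2))
}

#' Per-segment normalization of a heading-error series
#'
#' Divides the steady-frame error of each analyzed segment by its
#' first-frame error, so every normalized segment starts at exactly 1 and
#' segments with 1-degree and 80-degree heading shifts become comparable.
#' The first segment is excluded from analysis: it has no prior neural
#' activity to overcome, so its estimate stabilizes immediately and its
#' normalization would not measure re-convergence. Transition frames are
#' likewise excluded (they are the error spike being recovered from).
#' Segments whose first-frame error is zero are skipped with a warning
#' (undefined normalization).
#'
#' @param trial A per-frame decode data frame from [run_condition_trial()]
#'   (needs columns `error`, `segment`, `is_transition`), or a numeric
#'   error vector together with `segment` and `is_transition` vectors.
#' @param segment,is_transition Per-frame annotations when `trial` is a
#'   numeric vector.
#' @return Named list of normalized numeric vectors, one per analyzed
#'   segment (`"2"`, `"3"`, ...), with attribute `skipped` counting
#'   segments dropped for zero first-frame error.
#' @export
normalize_segments <- function(trial, segment = NULL, is_transition = NULL) {
  if (is.data.frame(trial)) {
    err <- trial$error; segment <- trial$segment
    is_transition <- trial$is_transition
  } else err <- as.numeric(trial)
  segs <- sort(unique(segment))
  segs <- segs[segs > min(segs)]           # first segment excluded
  out <- list(); skipped <- 0L
  for (s in segs) {
    y <- err[segment == s & !is_transition]
    if (length(y) == 0L) next
    if (y[1] == 0) {
      warning(sprintf("segment %d skipped: zero first-frame error", s))
      skipped <- skipped + 1L
      next
    }
    out[[as.character(s)]] <- y / y[1]
  }
  attr(out, "skipped") <- skipped
  out
}

#' Fit a decreasing 4-parameter logistic to an error time series
#'
#' Least-squares fit of
#' `y(t) = lower + (upper - lower) / (1 + exp(rate * (t - midpoint)))`,
#' which decreases from `upper` to `lower` for `rate > 0`. The convergence
#' frame — the latency measure — is the frame at which the curve has
#' dropped by 98% of `upper - lower`, available in closed form as
#' `midpoint + log(49) / rate`.
#'
#' A constant series yields the degenerate fit `upper == lower` with
#' convergence frame 0, flagged `converged = FALSE`; a fit that fails to
#' converge or comes out increasing (`rate <= 0`) is flagged the same way
#' so callers can exclude it from parameter averages.
#'
#' @param y Numeric series (>= 8 frames).
#' @param frames Frame indices. Default `seq_along(y)`.
#' @return An object of class `logistic_fit`: list with `upper`, `lower`,
#'   `rate`, `midpoint`, `convergence_frame`, `converged`, `fitted`.
#' @export
fit_logistic <- function(y, frames = seq_along(y)) {
  y <- as.numeric(y)
  if (length(y) < 8L) stop("need at least 8 frames to fit")
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps * max(1, abs(y[1]))) {
    return(logistic_fit(y[1], y[1], NA_real_, NA_real_, 0, FALSE,
                        rep(y[1], length(y))))
  }
  half <- min(y) + rng / 2
  mid0 <- frames[which(y <= half)[1]]
  if (is.na(mid0)) mid0 <- stats::median(frames)
  start <- list(upper = max(y), lower = min(y), rate = 0.5, midpoint = mid0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + exp(rate * (t - midpoint))),
      data = data.frame(t = frames, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(logistic_fit(max(y), min(y), NA_real_, NA_real_, NA_real_,
                        FALSE, rep(NA_real_, length(y))))
  }
  p <- as.list(stats::coef(fit))
  ok <- is.finite(p$rate) && p$rate > 0 && p$upper >= p$lower
  cf <- logistic_convergence_frame(p$upper, p$lower, p$rate, p$midpoint)
  logistic_fit(p$upper, p$lower, p$rate, p$midpoint, cf, ok,
               stats::fitted(fit))
}

logistic_fit <- function(upper, lower, rate, midpoint, convergence_frame,
                         converged, fitted) {
  structure(list(upper = upper, lower = lower, rate = rate,
                 midpoint = midpoint,
                 convergence_frame = convergence_frame,
                 converged = converged, fitted = fitted),
            class = "logistic_fit")
}

#' Closed-form 98%-drop frame of a decreasing logistic
#'
#' Solves `y(t) = upper - 0.98 (upper - lower)` for the logistic of
#' [fit_logistic()]: `t = midpoint + log(0.98 / 0.02) / rate`. Degenerate
#' curves (`upper == lower`) converge at frame 0 by convention.
#'
#' @param upper,lower,rate,midpoint Logistic parameters.
#' @param level Drop fraction. Default 0.98.
#' @return The convergence frame.
#' @export
logistic_convergence_frame <- function(upper, lower, rate, midpoint,
                                       level = 0.98) {
  if (!is.finite(rate) || upper <= lower) return(0)
  midpoint + log(level / (1 - level)) / rate
}

#' Evaluate the 4-parameter logistic
#'
#' @param frames Frame indices.
#' @param upper,lower,rate,midpoint Parameters as in [fit_logistic()].
#' @return Curve values.
#' @export
logistic_curve <- function(frames, upper, lower, rate, midpoint) {
  lower + (upper - lower) / (1 + exp(rate * (frames - midpoint)))
}

#' Experiment condition
#'
#' Defines one tuning regime to be compared by [run_experiment()]:
#' `dynamic` (rolling-horizon efficient encoding, horizon 1, 10 or 30
#' frames), `static_uniform` (tuning derived once from a uniform speed
#' distribution, default range 0-5.3 degrees/frame) or `static_aggregate`
#' (tuning derived once from the distribution pooled over every frame of
#' the whole stimulus set, computed in a pre-pass).
#'
#' @param label One of `"dynamic"`, `"static_uniform"`,
#'   `"static_aggregate"`.
#' @param horizon_frames Rolling-horizon length (dynamic only).
#'   Default 10.
#' @param uniform_range Speed range of the uniform baseline
#'   (degrees/frame). Default `c(0, 5.3)`.
#' @return An object of class `condition` with a unique `name`.
#' @export
condition <- function(label = c("dynamic", "static_uniform",
                                "static_aggregate"),
                      horizon_frames = 10L, uniform_range = c(0, 5.3)) {
  label <- match.arg(label)
  horizon_frames <- as.integer(horizon_frames)
  if (label == "dynamic" && (is.na(horizon_frames) || horizon_frames < 1L))
    stop("horizon_frames must be >= 1")
  if (label == "static_uniform" &&
      (uniform_range[1] != 0 || uniform_range[2] <= 0))
    stop("uniform_range must be c(0, max) with max > 0")
  name <- if (label == "dynamic") sprintf("dynamic_h%d", horizon_frames)
          else label
  structure(list(label = label, name = name,
                 horizon_frames = horizon_frames,
                 uniform_range = uniform_range),
            class = "condition")
}

#' Run one condition on one rendered trial
#'
#' Streams the trial's flow fields through the full pipeline: (dynamic
#' only) update the rolling horizon and re-derive the tuning each frame,
#' compute the pooled direction-marginal MT signal, match it against the
#' template bank, advance the recurrent MSTd state, decode, and score
#' against ground truth. When the state carries no signal the previous
#' estimate is held (initially the image center).
#'
#' @param flows List of [flow_field()]s (one per frame).
#' @param trajectory The [make_trajectory()] that produced them.
#' @param cond A [condition()].
#' @param config The [mt_config()].
#' @param bank The [template_bank()].
#' @param lambda,inhibition Recurrent parameters; see [mstd_state()].
#' @param static_tuning Pre-derived tuning for static conditions.
#' @param bins Histogram bins for dynamic pooling. Default 128.
#' @param sigma_floor Optional bandwidth floor passed to [derive_tuning()].
#' @return Per-frame data frame: `frame`, `segment`, `is_transition`,
#'   `est_az`, `est_el`, `margin`, `truth_az`, `truth_el`, `error`,
#'   `error_az`, `error_el`, `degenerate`.
#' @export
run_condition_trial <- function(flows, trajectory, cond, config, bank,
                                lambda = 0.05, inhibition = 1,
                                static_tuning = NULL, bins = 128L,
                                sigma_floor = NULL) {
  stopifnot(inherits(cond, "condition"), inherits(config, "mt_config"))
  n <- length(flows)
  fr <- trajectory$frames
  if (nrow(fr) != n) stop("flow sequence and trajectory length differ")

  dynamic <- cond$label == "dynamic"
  if (!dynamic && is.null(static_tuning))
    stop("static conditions need a pre-derived static_tuning")
  horizon <- if (dynamic) rolling_horizon(cond$horizon_frames, bins)
  tuning <- static_tuning
  state <- mstd_state(bank, lambda = lambda, inhibition = inhibition)
  prev <- c(0, 0)

  out <- vector("list", n)
  for (t in seq_len(n)) {
    degen <- FALSE
    if (dynamic) {
      dist <- update_horizon(horizon, flows[[t]])
      degen <- dist$point_mass
      tuning <- derive_tuning(dist, config$n_speeds,
                              sigma_floor = sigma_floor,
                              provenance = "dynamic",
                              horizon_frames = cond$horizon_frames)
    }
    m <- mt_direction_signal(flows[[t]], tuning, config)
    drive <- feedforward_match(m, bank)
    state <- recurrent_step(state, drive)
    est <- tryCatch(decode_heading(state), error = function(e) NULL)
    azel <- if (is.null(est)) prev else c(est$azimuth, est$elevation)
    prev <- azel
    truth <- c(fr$heading_az[t], fr$heading_el[t])
    e <- heading_error(azel, truth)
    out[[t]] <- data.frame(
      frame = t, segment = fr$segment[t],
      is_transition = fr$is_transition[t],
      est_az = azel[1], est_el = azel[2],
      margin = if (is.null(est)) NA_real_ else est$margin,
      truth_az = truth[1], truth_el = truth[2],
      error = e$total, error_az = e$azimuth, error_el = e$elevation,
      degenerate = degen)
  }
  do.call(rbind, out)
}

# deterministic fan-out of child seeds from one master seed
child_seed <- function(seed, stage, k = 0L) {
  base <- (as.numeric(seed) %% 1e6) * 1009 + stage * 97003 + k * 131
  as.integer(base %% (2^31 - 1)) + 1L
}

#' Run a full tuning-comparison experiment
#'
#' Generates `n_trials` seeded stimulus trials (cluttered-scene
#' trajectories following the five-segment protocol, rendered to flow at
#' `mt_grid` resolution, optionally noised), runs every condition on the
#' identical stimuli, and summarizes: converged heading error (final
#' steady frame of segments 2-5) with bootstrap 95% confidence intervals,
#' frame-15 error, per-frame mean error, per-segment normalized series
#' with averaged logistic fits and the 98%-drop convergence frame, the
#' difference-to-static-uniform curve, transition-spike statistics, and
#' degenerate-tuning frame counts. All randomness fans out from `seed`.
#'
#' @param conditions List of [condition()]s. Default: dynamic (horizon
#'   10), static-uniform, static-aggregate.
#' @param n_trials Number of stimulus trials. Default 10.
#' @param seed Master seed.
#' @param mt_grid,mstd_grid,n_directions,n_speeds,fov_deg Model scale
#'   parameters (see [mt_config()] and [template_bank()]).
#' @param scene_kind Scene type for every trial. Default `"cluttered"`.
#' @param scene_depth_ranges For cluttered scenes, a list of depth ranges
#'   (meters) cycled across trials. The default alternates an enclosed,
#'   close-surface environment (1.5-12 m, the geometry of a warehouse
#'   corridor with shelving a few meters away) with an open,
#'   deep-depth-variation one (3-250 m, neighborhood-like), emulating a
#'   50/50 mix of indoor and outdoor stimuli whose flow-speed
#'   distributions differ strongly.
#' @param noise_sigma Flow estimation noise (degrees/frame). Default 0.
#' @param sky_outlier_rate Outlier rate on sky pixels when noise is on.
#' @param lambda,inhibition Recurrent parameters.
#' @param bins Histogram bins. Default 128.
#' @param n_boot Bootstrap resamples. Default 2000.
#' @param sigma_floor Optional bandwidth floor for dynamic tuning.
#' @return An object of class `condition_summary`; see
#'   [summarize_conditions()] for the per-condition fields.
#' @export
run_experiment <- function(conditions = list(condition("dynamic"),
                                             condition("static_uniform"),
                                             condition("static_aggregate")),
                           n_trials = 10L, seed = 1L,
                           mt_grid = 48L, mstd_grid = 24L,
                           n_directions = 24L, n_speeds = 7L, fov_deg = 90,
                           scene_kind = "cluttered",
                           scene_depth_ranges = list(c(1.5, 12), c(3, 250)),
                           noise_sigma = 0,
                           sky_outlier_rate = 0.02,
                           lambda = 0.05, inhibition = 1, bins = 128L,
                           n_boot = 2000L, sigma_floor = NULL) {
  stopifnot(all(vapply(conditions, inherits, logical(1), "condition")))
  names(conditions) <- vapply(conditions, `[[`, character(1), "name")
  if (anyDuplicated(names(conditions)))
    stop("condition names must be unique")
  config <- mt_config(grid = mt_grid, n_directions = n_directions,
                      n_speeds = n_speeds, fov_deg = fov_deg)
  bank <- template_bank(mstd_grid, config)

  trials <- lapply(seq_len(n_trials), function(i) {
    dr <- scene_depth_ranges[[(i - 1L) %% length(scene_depth_ranges) + 1L]]
    scene <- depth_scene(scene_kind, depth_range = dr,
                         seed = child_seed(seed, 1L, i))
    traj <- make_trajectory(child_seed(seed, 2L, i), grid = mt_grid,
                            fov_deg = fov_deg, scene = scene)
    flows <- render_trajectory_flow(scene, traj)
    if (noise_sigma > 0) {
      flows <- lapply(seq_along(flows), function(t)
        add_estimation_noise(flows[[t]], noise_sigma, sky_outlier_rate,
                             seed = child_seed(seed, 3L, i * 1000L + t)))
    }
    list(trajectory = traj, flows = flows)
  })

  # pre-pass for the aggregate baseline: pool every frame of every trial
  static_tunings <- list()
  labs <- vapply(conditions, `[[`, character(1), "label")
  if ("static_aggregate" %in% labs) {
    mags <- unlist(lapply(trials, function(tr)
      lapply(tr$flows, pool_flow_magnitudes)), use.names = FALSE)
    agg <- speed_histogram(mags, bins)
    static_tunings$static_aggregate <-
      derive_tuning(agg, n_speeds, provenance = "static_aggregate")
  }
  if ("static_uniform" %in% labs) {
    rng <- conditions[[which(labs == "static_uniform")[1]]]$uniform_range
    static_tunings$static_uniform <-
      derive_tuning(uniform_speed_distribution(rng[2], bins), n_speeds,
                    provenance = "static_uniform")
  }

  runs <- lapply(conditions, function(cond) {
    lapply(trials, function(tr)
      run_condition_trial(tr$flows, tr$trajectory, cond, config, bank,
                          lambda = lambda, inhibition = inhibition,
                          static_tuning = static_tunings[[cond$label]],
                          bins = bins, sigma_floor = sigma_floor))
  })

  summarize_conditions(runs, conditions, seed = seed, n_boot = n_boot,
                       params = list(
                         n_trials = n_trials, mt_grid = mt_grid,
                         mstd_grid = mstd_grid, n_directions = n_directions,
                         n_speeds = n_speeds, fov_deg = fov_deg,
                         scene_kind = scene_kind, noise_sigma = noise_sigma,
                         lambda = lambda, inhibition = inhibition,
                         bins = bins, seed = seed))
}

#' Summarize per-condition decode runs
#'
#' Computes the metrics of a tuning-comparison experiment from raw
#' per-trial decode frames. Exposed separately so cached runs can be
#' re-summarized.
#'
#' @param runs Named list (by condition) of lists of per-trial decode data
#'   frames from [run_condition_trial()].
#' @param conditions The [condition()]s, in the same order.
#' @param seed Seed for the bootstrap.
#' @param n_boot Bootstrap resamples. Default 2000.
#' @param params Run parameters to carry along.
#' @return A `condition_summary`: per condition, `converged_error` /
#'   `frame15_error` (mean, CI, values), `fit` (averaged logistic
#'   parameters), `convergence_frame`, `mean_error_by_frame` (with CIs),
#'   `diff_vs_static_uniform`, `transition_spike`, `degenerate_frames`,
#'   `failed_fits`.
#' @export
summarize_conditions <- function(runs, conditions, seed = 1L,
                                 n_boot = 2000L, params = list()) {
  names(conditions) <- vapply(conditions, `[[`, character(1), "name")
  res <- list()
  su_fit <- NULL

  for (nm in names(runs)) {
    trials <- runs[[nm]]
    conv <- unlist(lapply(trials, segment_final_errors, which = "last"))
    f15 <- unlist(lapply(trials, segment_final_errors, which = 15L))
    norm <- lapply(trials, normalize_segments)
    fits <- lapply(unlist(norm, recursive = FALSE), fit_logistic)
    ok <- vapply(fits, `[[`, logical(1), "converged")
    avg <- if (any(ok)) {
      pars <- vapply(fits[ok], function(f)
        c(f$upper, f$lower, f$rate, f$midpoint), numeric(4))
      rowMeans(pars)
    } else rep(NA_real_, 4)
    cf <- if (any(ok))
      logistic_convergence_frame(avg[1], avg[2], avg[3], avg[4]) else NA_real_

    err_mat <- vapply(trials, `[[`, numeric(nrow(trials[[1]])), "error")
    mean_err <- rowMeans(err_mat)
    ci <- apply(err_mat, 1, function(x)
      boot_ci(x, n_boot = min(500L, n_boot),
              seed = child_seed(seed, 5L))$ci)

    spike <- transition_spike(trials[[1]])
    spikes <- vapply(trials, transition_spike, numeric(2))

    res[[nm]] <- list(
      condition = conditions[[nm]],
      converged_error = boot_ci(conv, n_boot, child_seed(seed, 6L)),
      frame15_error = boot_ci(f15, n_boot, child_seed(seed, 7L)),
      converged_values = conv,
      fit = list(upper = avg[1], lower = avg[2], rate = avg[3],
                 midpoint = avg[4]),
      convergence_frame = cf,
      failed_fits = sum(!ok),
      mean_error_by_frame = data.frame(
        frame = trials[[1]]$frame, mean = mean_err,
        lo = ci[1, ], hi = ci[2, ]),
      normalized = norm,
      transition_spike = list(transition = mean(spikes[1, ]),
                              settled = mean(spikes[2, ])),
      degenerate_frames = sum(vapply(trials, function(tr)
        sum(tr$degenerate), numeric(1)))
    )
    if (conditions[[nm]]$label == "static_uniform") su_fit <- res[[nm]]$fit
  }

  # normalized error relative to the static-uniform best-fitting curve
  if (!is.null(su_fit) && is.finite(su_fit$rate)) {
    for (nm in names(res)) {
      segs <- unlist(res[[nm]]$normalized, recursive = FALSE)
      lens <- vapply(segs, length, integer(1))
      len <- min(lens)
      ref <- logistic_curve(seq_len(len), su_fit$upper, su_fit$lower,
                            su_fit$rate, su_fit$midpoint)
      diffs <- vapply(segs, function(y) y[seq_len(len)] - ref,
                      numeric(len))
      res[[nm]]$diff_vs_static_uniform <- data.frame(
        frame = seq_len(len), mean = rowMeans(diffs))
    }
  }

  structure(list(conditions = res, runs = runs, params = params,
                 seed = seed, n_boot = n_boot),
            class = "condition_summary")
}

# error at a given steady frame (or the last) of each analyzed segment
segment_final_errors <- function(trial, which = "last") {
  segs <- sort(unique(trial$segment))
  segs <- segs[segs > min(segs)]
  vapply(segs, function(s) {
    y <- trial$error[trial$segment == s & !trial$is_transition]
    if (identical(which, "last")) y[length(y)]
    else y[min(as.integer(which), length(y))]
  }, numeric(1))
}

# c(mean transition-frame error, mean over last 5 steady frames following)
transition_spike <- function(trial) {
  segs <- sort(unique(trial$segment))
  segs <- segs[segs > min(segs)]
  tr_err <- st_err <- numeric(0)
  for (s in segs) {
    tr_err <- c(tr_err, trial$error[trial$segment == s & trial$is_transition])
    y <- trial$error[trial$segment == s & !trial$is_transition]
    st_err <- c(st_err, utils::tail(y, 5))
  }
  c(mean(tr_err), mean(st_err))
}

#' Bootstrap mean and percentile confidence interval
#'
#' @param x Numeric observations.
#' @param n_boot Resamples. Default 2000.
#' @param seed Seed.
#' @param conf Confidence level. Default 0.95.
#' @return List with `mean`, `ci` (length 2), `n`.
#' @export
boot_ci <- function(x, n_boot = 2000L, seed = 1L, conf = 0.95) {
  x <- x[is.finite(x)]
  means <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(sample(x, replace = TRUE)), numeric(1)))
  a <- (1 - conf) / 2
  list(mean = mean(x),
       ci = unname(stats::quantile(means, c(a, 1 - a))),
       n = length(x))
}

#' One-sided bootstrap test that `x` has a smaller mean than `y`
#'
#' Paired bootstrap over matched observations (same trial-segments run
#' under two conditions): resamples the paired differences and reports the
#' fraction of resampled mean differences at or above zero as the p-value
#' for the hypothesis `mean(x) < mean(y)`.
#'
#' @param x,y Paired numeric observations.
#' @param n_boot Resamples. Default 2000.
#' @param seed Seed.
#' @return List with `p`, `mean_diff`, `n`.
#' @export
boot_p_less <- function(x, y, n_boot = 2000L, seed = 1L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  means <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(sample(d, replace = TRUE)), numeric(1)))
  list(p = mean(means >= 0), mean_diff = mean(d), n = length(d))
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("condition_summary:", length(x$conditions), "conditions,",
      x$params$n_trials, "trials, seed", x$seed, "\n")
  for (nm in names(x$conditions)) {
    r <- x$conditions[[nm]]
    cat(sprintf(
      "  %-18s converged %.2f deg [%.2f, %.2f], convergence frame %s, %d degenerate frames\n",
      nm, r$converged_error$mean, r$converged_error$ci[1],
      r$converged_error$ci[2],
      ifelse(is.finite(r$convergence_frame),
             sprintf("%.1f", r$convergence_frame), "NA"),
      r$degenerate_frames))
  }
  invisible(x)
}

#' Plot mean heading error per frame for each condition
#'
#' Base-graphics rendition of the per-frame mean error with bootstrap
#' bands, one line per condition.
#'
#' @param x A `condition_summary`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.condition_summary <- function(x, ...) {
  mats <- lapply(x$conditions, function(r) r$mean_error_by_frame$mean)
  m <- do.call(cbind, mats)
  graphics::matplot(m, type = "l", lty = 1, lwd = 2,
                    xlab = "frame", ylab = "mean heading error (deg)", ...)
  graphics::legend("topright", legend = names(x$conditions),
                   col = seq_len(ncol(m)), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Write per-trial decode CSVs and a per-condition summary JSON
#'
#' @param summary A `condition_summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_outputs <- function(summary, dir) {
  stopifnot(inherits(summary, "condition_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(summary$runs)) {
    for (i in seq_along(summary$runs[[nm]])) {
      utils::write.csv(
        summary$runs[[nm]][[i]],
        file.path(dir, sprintf("decodes_%s_trial%02d.csv", nm, i)),
        row.names = FALSE)
    }
  }
  js <- lapply(summary$conditions, function(r) list(
    converged_error = r$converged_error,
    frame15_error = r$frame15_error,
    fit = r$fit,
    convergence_frame = r$convergence_frame,
    failed_fits = r$failed_fits,
    transition_spike = r$transition_spike,
    degenerate_frames = r$degenerate_frames))
  writeLines(jsonlite::toJSON(list(conditions = js, params = summary$params),
                              digits = NA, auto_unbox = TRUE, na = "null"),
             file.path(dir, "summary.json"))
  invisible(dir)
}
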