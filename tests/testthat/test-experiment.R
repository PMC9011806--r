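gv <- function(azel) {
  v <- c(tan(azel[1] * pi / 180), tan(azel[2] * pi / 180), 1)
  v / sqrt(sum(v^2))
}

test_that("heading error follows the 3-D gaze-vector geometry", {
  expect_equal(heading_error(c(5, -3), c(5, -3))$total, 0)
  e <- heading_error(c(10, 0), c(0, 0))
  expect_equal(e$total, 10, tolerance = 1e-9)
  expect_equal(e$azimuth, 10)
  expect_equal(e$elevation, 0)
  e2 <- heading_error(c(3, 4), c(0, 0))
  oracle <- acos(sum(gv(c(3, 4)) * gv(c(0, 0)))) * 180 / pi
  expect_equal(e2$total, oracle, tolerance = 1e-12)
  expect_equal(e2$total, 5, tolerance = 0.02)  # small-angle approximation
})

test_that("segment normalization is scale invariant and excludes segment 1", {
  segment <- rep(1:5, each = 10)
  trans <- rep(FALSE, 50)
  err <- rep(2, 50)
  norm <- normalize_segments(err, segment, trans)
  expect_equal(names(norm), c("2", "3", "4", "5"))
  expect_true(all(unlist(norm) == 1))

  # halving series normalizes identically regardless of initial magnitude
  dec <- 0.5^(0:9)
  err2 <- c(rep(1, 10), 1 * dec, 80 * dec, 7 * dec, 0.1 * dec)
  norm2 <- normalize_segments(err2, segment, trans)
  for (s in names(norm2)) expect_equal(norm2[[s]], dec, tolerance = 1e-12)

  # zero first-frame error skips the segment with a warning
  err3 <- err2; err3[11] <- 0
  expect_warning(norm3 <- normalize_segments(err3, segment, trans),
                 "zero first-frame")
  expect_equal(names(norm3), c("3", "4", "5"))
  expect_equal(attr(norm3, "skipped"), 1L)
})

test_that("logistic fits recover known parameters and the 98% frame", {
  frames <- 1:30
  y <- logistic_curve(frames, upper = 1, lower = 0.1, rate = 0.6,
                      midpoint = 8)
  fit <- fit_logistic(y, frames)
  expect_true(fit$converged)
  expect_equal(fit$upper, 1, tolerance = 1e-6)
  expect_equal(fit$lower, 0.1, tolerance = 1e-6)
  expect_equal(fit$rate, 0.6, tolerance = 1e-6)
  expect_equal(fit$midpoint, 8, tolerance = 1e-6)

  # place the 98% drop exactly at frame 15: midpoint = 15 - log(49)/rate
  rate <- 0.9
  mid <- 15 - log(49) / rate
  y2 <- logistic_curve(frames, 1, 0, rate, mid)
  fit2 <- fit_logistic(y2, frames)
  expect_equal(fit2$convergence_frame, 15, tolerance = 0.01)

  # constant series degenerates to a flagged zero-latency fit
  fit3 <- fit_logistic(rep(0.7, 20))
  expect_false(fit3$converged)
  expect_equal(fit3$convergence_frame, 0)
  expect_equal(fit3$upper, fit3$lower)
  expect_error(fit_logistic(1:5), "at least 8 frames")
})

test_that("bootstrap helpers are seeded and sensible", {
  x <- c(1, 2, 3, 4, 5)
  b1 <- boot_ci(x, n_boot = 500, seed = 9)
  b2 <- boot_ci(x, n_boot = 500, seed = 9)
  expect_identical(b1, b2)
  expect_equal(b1$mean, 3)
  expect_true(b1$ci[1] <= 3 && b1$ci[2] >= 3)
  set.seed(10)
  lo <- rnorm(40, 1); hi <- lo + 1
  p <- boot_p_less(lo, hi, n_boot = 500, seed = 2)
  expect_lt(p$p, 0.01)
  expect_equal(p$mean_diff, -1, tolerance = 1e-12)
})

test_that("a condition trial streams the pipeline deterministically", {
  sc <- depth_scene("cluttered", seed = 61)
  tr <- make_trajectory(61, grid = 24, scene = sc)
  flows <- render_trajectory_flow(sc, tr)
  cfg <- mt_config(grid = 24, n_directions = 8, n_speeds = 7)
  bank <- template_bank(8, cfg)
  cond <- condition("dynamic", horizon_frames = 5)
  t1 <- run_condition_trial(flows, tr, cond, cfg, bank)
  t2 <- run_condition_trial(flows, tr, cond, cfg, bank)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 162L)
  expect_true(all(t1$error >= 0))
  expect_true(all(abs(t1$est_az) <= 45 & abs(t1$est_el) <= 45))

  su <- derive_tuning(uniform_speed_distribution(5.3), 7,
                      provenance = "static_uniform")
  ts <- run_condition_trial(flows, tr, condition("static_uniform"), cfg,
                            bank, static_tuning = su)
  expect_equal(nrow(ts), 162L)
  expect_error(
    run_condition_trial(flows, tr, condition("static_uniform"), cfg, bank),
    "pre-derived")
})

test_that("experiment summaries are reproducible end to end", {
  conds <- list(condition("dynamic", horizon_frames = 5),
                condition("static_uniform"))
  run1 <- run_experiment(conds, n_trials = 2, seed = 3, mt_grid = 24,
                         mstd_grid = 8, n_directions = 8, n_boot = 200)
  run2 <- run_experiment(conds, n_trials = 2, seed = 3, mt_grid = 24,
                         mstd_grid = 8, n_directions = 8, n_boot = 200)
  expect_identical(run1$conditions$dynamic_h5$converged_error,
                   run2$conditions$dynamic_h5$converged_error)
  expect_identical(run1$runs, run2$runs)
  expect_equal(names(run1$conditions), c("dynamic_h5", "static_uniform"))
  r <- run1$conditions$dynamic_h5
  expect_equal(r$converged_error$n, 8L)   # 4 segments x 2 trials
  expect_equal(nrow(r$mean_error_by_frame), 162L)
  expect_true(!is.null(r$diff_vs_static_uniform) ||
              !is.finite(run1$conditions$static_uniform$fit$rate))

  dir <- withr::local_tempdir()
  write_experiment_outputs(run1, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_length(list.files(dir, pattern = "^decodes_.*csv$"), 4L)
})
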