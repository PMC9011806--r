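make_uniform_flow <- function(grid, u, v) {
  flow_field(matrix(u, grid, grid), matrix(v, grid, grid))
}

test_that("macrocolumn size is directions times speeds", {
  expect_equal(macrocolumn_size(mt_config()), 168L)
  expect_equal(macrocolumn_size(mt_config(n_directions = 8, n_speeds = 3)),
               24L)
})

test_that("rightward flow at a preferred speed peaks the matching channel", {
  g <- 16
  cfg <- mt_config(grid = g, n_directions = 8, n_speeds = 7)
  ts <- derive_tuning(uniform_speed_distribution(7), 7)
  mu3 <- ts$curves$mu[3]
  fl <- make_uniform_flow(g, mu3, 0)   # rightward at exactly mu_3
  r <- mt_respond(fl, ts, cfg)
  expect_equal(dim(r$activity), c(g, g, 8, 7))
  interior <- 5:12
  expect_equal(max(r$activity), 1, tolerance = 1e-9)
  expect_true(all(abs(r$activity[interior, interior, 1, 3] - 1) < 1e-9))
  # opposite direction channel (180 deg) is silent at that speed
  expect_true(all(r$activity[, , 5, 3] < 1e-8))
  expect_true(all(r$activity >= 0 & r$activity <= 1 + 1e-12))
})

test_that("a speed midway between two equal-sigma curves excites them equally", {
  g <- 8
  cfg <- mt_config(grid = g, n_directions = 8, n_speeds = 7)
  ts <- derive_tuning(uniform_speed_distribution(7), 7)
  s_mid <- mean(ts$curves$mu[3:4])
  fl <- make_uniform_flow(g, s_mid, 0)
  r <- mt_respond(fl, ts, cfg)
  expect_equal(r$activity[4, 4, 1, 3], r$activity[4, 4, 1, 4],
               tolerance = 1e-9)
})

test_that("pooling spreads a single pixel by the normalized kernel", {
  g <- 16
  cfg <- mt_config(grid = g, n_directions = 8, n_speeds = 7)
  ts <- derive_tuning(uniform_speed_distribution(7), 7)
  u <- matrix(0, g, g); u[8, 8] <- ts$curves$mu[4]
  fl <- flow_field(u, matrix(0, g, g))
  r <- mt_respond(fl, ts, cfg)
  ch <- r$activity[, , 1, 4]
  # kernel support is 9x9 and mass is conserved for an interior pixel
  expect_equal(sum(ch), 1, tolerance = 1e-9)
  expect_true(all(ch[8 + 5:8, ] == 0))
  expect_true(all(ch[, 8 + 5:8] == 0))
  expect_equal(which(ch == max(ch), arr.ind = TRUE)[1, ], c(row = 8, col = 8))
})

test_that("zero and invalid flow produce zero activity", {
  g <- 8
  cfg <- mt_config(grid = g, n_directions = 8, n_speeds = 7)
  ts <- derive_tuning(uniform_speed_distribution(7), 7)
  fl <- make_uniform_flow(g, 0, 0)
  expect_true(all(mt_respond(fl, ts, cfg)$activity == 0))
  fl2 <- flow_field(matrix(3, g, g), matrix(0, g, g),
                    valid = matrix(FALSE, g, g))
  expect_true(all(mt_respond(fl2, ts, cfg)$activity == 0))
})

test_that("grid and tuning-size mismatches are rejected", {
  cfg <- mt_config(grid = 8, n_directions = 8, n_speeds = 7)
  ts <- derive_tuning(uniform_speed_distribution(7), 7)
  expect_error(mt_respond(make_uniform_flow(12, 1, 0), ts, cfg),
               "does not match")
  ts5 <- derive_tuning(uniform_speed_distribution(7), 5)
  expect_error(mt_respond(make_uniform_flow(8, 1, 0), ts5, cfg),
               "expects 7 speeds")
})

test_that("direction marginal equals the speed-summed full response", {
  fl <- sample_flow(grid = 16, seed = 31)
  cfg <- mt_config(grid = 16, n_directions = 8, n_speeds = 7)
  ts <- derive_tuning(build_speed_distribution(fl), 7)
  full <- mt_respond(fl, ts, cfg)$activity
  marg <- mt_direction_signal(fl, ts, cfg)
  ref <- matrix(apply(full, c(1, 2, 3), sum), 16 * 16, 8)
  expect_equal(marg, ref, tolerance = 1e-12)
})

test_that("retuning changes which rank responds to a given speed", {
  g <- 8
  cfg <- mt_config(grid = g, n_directions = 8, n_speeds = 7)
  wide <- derive_tuning(uniform_speed_distribution(50), 7)
  narrow <- derive_tuning(uniform_speed_distribution(5), 7)
  pop <- mt_population(cfg, wide)
  fl <- make_uniform_flow(g, 2, 0)   # speed 2 deg/frame
  r_wide <- respond(pop, fl)
  pop <- retune(pop, narrow)
  r_narrow <- respond(pop, fl)
  prof_wide <- apply(r_wide$activity[4, 4, 1, , drop = FALSE], 4, max)
  prof_narrow <- apply(r_narrow$activity[4, 4, 1, , drop = FALSE], 4, max)
  # wide set: speed 2 sits below the slowest peak (7.1), weak low-rank hit
  expect_equal(which.max(prof_wide), 1L)
  expect_lt(max(prof_wide), 0.6)
  # narrow set: speed 2 sits near a mid-rank peak, strong response
  expect_equal(which.max(prof_narrow), 3L)
  expect_gt(max(prof_narrow), 0.85)
  # retune to the identical set reproduces responses bitwise
  pop2 <- retune(pop, narrow)
  expect_identical(respond(pop2, fl)$activity, r_narrow$activity)
  # rank order of peaks is always preserved
  expect_true(!is.unsorted(pop2$tuning$curves$mu))
})

test_that("matched tuning covers more pixels than a mismatched static set", {
  fl <- sample_flow(grid = 24, seed = 33)
  m <- flow_speed(fl)[fl$valid]
  matched <- derive_tuning(build_speed_distribution(fl), 7)
  mismatched <- derive_tuning(uniform_speed_distribution(50), 7)
  covered <- function(ts) {
    mean(vapply(m, function(s)
      any(abs(s - ts$curves$mu) <= 2 * ts$curves$sigma), logical(1)))
  }
  expect_gt(covered(matched), covered(mismatched))
})
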