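test_that("trajectories follow the five-segment protocol deterministically", {
  tr <- make_trajectory(101, grid = 64)
  expect_equal(nrow(tr$frames), 162L)  # 5 x 30 + 4 x 3
  expect_equal(sum(!tr$frames$is_transition), 150L)
  expect_equal(sum(tr$frames$is_transition), 12L)
  tr2 <- make_trajectory(101, grid = 64)
  expect_identical(tr$frames, tr2$frames)
  for (seed in 1:10) {
    t3 <- make_trajectory(seed, grid = 32)
    expect_true(all(t3$frames$speed >= 1 & t3$frames$speed <= 20))
    expect_true(t3$start_height >= 1 && t3$start_height <= 5)
  }
  expect_error(make_trajectory(1, speed_range = c(0.5, 25)), "speed_range")
  expect_error(make_trajectory(1, height_range = c(0.2, 9)), "height_range")
})

test_that("transition frames interpolate heading and speed linearly", {
  tr <- make_trajectory(7, grid = 64)
  fr <- tr$frames
  i <- which(fr$is_transition)[1:3]  # first transition block
  s_before <- fr$speed[i[1] - 1]; s_after <- fr$speed[i[3] + 1]
  expect_equal(fr$speed[i], s_before + (1:3) / 4 * (s_after - s_before),
               tolerance = 1e-12)
})

test_that("collision rejection keeps the camera clear of the ground", {
  sc <- depth_scene("ground_plane")
  for (seed in c(2, 9, 23)) {
    tr <- make_trajectory(seed, grid = 32, scene = sc)
    expect_true(all(tr$frames$pos_y > 0.5))
  }
})

test_that("rendered flow matches the closed-form wall oracle to 1e-6 deg", {
  set.seed(31)
  for (rep in 1:8) {
    g <- 12
    z0 <- runif(1, 20, 60)
    p1 <- c(runif(2, -2, 2), runif(1, -2, 2))
    p2 <- p1 + runif(3, -0.3, 0.3)
    sc <- depth_scene("frontoparallel_wall", wall_distance = z0)
    fl <- render_flow(sc, camera_pose(p1, grid = g),
                      camera_pose(p2, grid = g))
    or <- wall_flow_oracle(g, 90, z0, p1, p2)
    expect_lt(max(abs(fl$u - or$u)), 1e-6)
    expect_lt(max(abs(fl$v - or$v)), 1e-6)
  }
})

test_that("flow vanishes at the focus of expansion and radiates outward", {
  fl <- radial_flow(10, -5, grid = 64)
  m <- flow_speed(fl)
  pa <- deseflow:::pixel_angles(64, 90)
  idx <- which(m == min(m[fl$valid]), arr.ind = TRUE)[1, ]
  expect_lt(abs(pa$az[idx[1], idx[2]] - 10), 90 / 64 + 1e-9)
  expect_lt(abs(pa$el[idx[1], idx[2]] - (-5)), 90 / 64 + 1e-9)
  expect_equal(fl$heading, c(10, -5), tolerance = 1e-9)
  # all vectors point away from the FoE (positive radial component)
  dx <- pa$az - 10; dy <- pa$el - (-5)
  r <- sqrt(dx^2 + dy^2)
  far <- r > 5
  rad <- (fl$u * dx + fl$v * dy) / r
  expect_true(all(rad[far] > 0))
})

test_that("flow magnitude scales linearly with translation speed", {
  sc <- depth_scene("frontoparallel_wall", wall_distance = 40)
  d <- c(0.05, -0.02, 1); d <- d / sqrt(sum(d^2))
  g <- 32
  f1 <- render_flow(sc, camera_pose(c(0, 0, 0), grid = g),
                    camera_pose(0.05 * d, grid = g))
  f2 <- render_flow(sc, camera_pose(c(0, 0, 0), grid = g),
                    camera_pose(0.10 * d, grid = g))
  m1 <- flow_speed(f1); m2 <- flow_speed(f2)
  expect_true(all(abs(m2 / m1 - 2) < 0.01))
  ang1 <- atan2(f1$v, f1$u); ang2 <- atan2(f2$v, f2$u)
  dang <- abs(((ang2 - ang1) * 180 / pi + 180) %% 360 - 180)
  expect_true(all(dang < 0.1))
})

test_that("ground-plane flow decays with distance along the ground", {
  sc <- depth_scene("ground_plane")
  g <- 64
  fl <- render_flow(sc, camera_pose(c(0, 2, 0), grid = g),
                    camera_pose(c(0, 2, 0.3), grid = g))
  mid <- g / 2
  below <- which(fl$valid[, mid])          # rows below the horizon
  m <- flow_speed(fl)[below, mid]
  # rows are ordered top (far) to bottom (near): speeds must increase
  expect_true(all(diff(m) > 0))
  # sky is invalid, zero flow
  expect_false(any(fl$valid[1:(mid - 1), mid]))
})

test_that("ground scenes give long-tailed speed distributions, walls narrow ones", {
  g <- 48
  sc_g <- depth_scene("ground_plane")
  fl_g <- render_flow(sc_g, camera_pose(c(0, 2, 0), grid = g),
                      camera_pose(c(0, 2, 0.4), grid = g))
  sc_w <- depth_scene("frontoparallel_wall", wall_distance = 30)
  fl_w <- render_flow(sc_w, camera_pose(c(0, 2, 0), grid = g),
                      camera_pose(c(0, 2, 0.4), grid = g))
  m_g <- flow_speed(fl_g)[fl_g$valid]
  m_w <- flow_speed(fl_w)[fl_w$valid]
  iqr_rel <- function(x) stats::IQR(x) / stats::median(x)
  expect_gt(iqr_rel(m_g), 2 * iqr_rel(m_w))
  # ground flow spans orders of magnitude; wall flow is a narrow band
  expect_gt(max(m_g) / min(m_g), 10 * max(m_w) / min(m_w))
})

test_that("estimation noise has the stated statistics and is reproducible", {
  fl <- radial_flow(0, 0, grid = 100)   # 1e4 pixels
  ns <- add_estimation_noise(fl, sigma = 0.1, sky_outlier_rate = 0,
                             seed = 5)
  du <- ns$u - fl$u; dv <- ns$v - fl$v
  expect_equal(stats::sd(c(du, dv)), 0.1, tolerance = 0.02)
  expect_equal(mean(c(du, dv)), 0, tolerance = 0.005)
  ns2 <- add_estimation_noise(fl, sigma = 0.1, sky_outlier_rate = 0,
                              seed = 5)
  expect_identical(ns$u, ns2$u)
  # zero noise is the identity
  id <- add_estimation_noise(fl, sigma = 0, sky_outlier_rate = 0)
  expect_identical(id$u, fl$u)
})

test_that("sky pixels receive outliers at roughly the requested rate", {
  sc <- depth_scene("ground_plane")
  g <- 64
  fl <- render_flow(sc, camera_pose(c(0, 2, 0), grid = g),
                    camera_pose(c(0, 2, 0.3), grid = g))
  n_sky <- sum(!fl$valid)
  expect_gt(n_sky, 1000)
  ns <- add_estimation_noise(fl, sigma = 0, sky_outlier_rate = 0.1,
                             seed = 2)
  hit <- sum(ns$u[!fl$valid] != 0 | ns$v[!fl$valid] != 0)
  expect_gt(hit / n_sky, 0.05)
  expect_lt(hit / n_sky, 0.2)
  expect_true(all(ns$valid))  # noised field is a dense measurement
})
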