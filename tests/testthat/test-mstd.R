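# Shared small-scale pipeline pieces for template tests.
mstd_setup <- function(mt_grid = 32, bank_grid = 8, n_dir = 8) {
  cfg <- mt_config(grid = mt_grid, n_directions = n_dir, n_speeds = 7)
  list(cfg = cfg, bank = template_bank(bank_grid, cfg))
}

signal_for <- function(fl, cfg) {
  ts <- derive_tuning(build_speed_distribution(fl), 7)
  mt_direction_signal(fl, ts, cfg)
}

test_that("template spacing partitions the field of view evenly", {
  s <- mstd_setup(bank_grid = 8)
  expect_equal(bank_resolution_deg(s$bank), 90 / 8)
  expect_equal(diff(s$bank$az), rep(90 / 8, 7))
  expect_equal(s$bank$az[1], -45 + 90 / 16)
  b64 <- template_bank(64, mt_config(grid = 32))
  expect_equal(bank_resolution_deg(b64), 1.40625)
})

test_that("template drive equals the brute-force rectified-cosine match", {
  s <- mstd_setup(mt_grid = 24, bank_grid = 6)
  set.seed(41)
  for (rep in 1:3) {
    fl <- sample_flow(grid = 24, seed = 40 + rep)
    m <- signal_for(fl, s$cfg)
    fast <- feedforward_match(m, s$bank)
    slow <- brute_force_drive(m, s$bank)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
  # the full MT response (summed over speeds internally) gives the same
  fl <- sample_flow(grid = 24, seed = 44)
  ts <- derive_tuning(build_speed_distribution(fl), 7)
  r <- mt_respond(fl, ts, s$cfg)
  expect_equal(feedforward_match(r, s$bank),
               feedforward_match(mt_direction_signal(fl, ts, s$cfg), s$bank),
               tolerance = 1e-10)
})

test_that("radial flow drives the template at its focus of expansion", {
  s <- mstd_setup(mt_grid = 32, bank_grid = 8)
  for (k in c(11, 29, 47)) {
    i <- (k %% 8) + 1; j <- ((k * 3) %% 8) + 1
    fl <- radial_flow(s$bank$az[j], s$bank$el[i], grid = 32)
    drive <- feedforward_match(signal_for(fl, s$cfg), s$bank)
    win <- which(drive == max(drive), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(unname(win) - c(i, j))), 1)
  }
})

test_that("scaling all flow speeds leaves the winning template unchanged", {
  s <- mstd_setup(mt_grid = 32, bank_grid = 8)
  fl <- radial_flow(s$bank$az[3], s$bank$el[6], grid = 32)
  wide <- derive_tuning(uniform_speed_distribution(10), 7)
  d1 <- feedforward_match(mt_direction_signal(fl, wide, s$cfg), s$bank)
  fl3 <- flow_field(3 * fl$u, 3 * fl$v, fl$valid, fl$heading)
  d3 <- feedforward_match(mt_direction_signal(fl3, wide, s$cfg), s$bank)
  expect_equal(which.max(d1), which.max(d3))
})

test_that("zero MT activity yields zero drive everywhere", {
  s <- mstd_setup(mt_grid = 16, bank_grid = 4)
  m <- matrix(0, 16 * 16, 8)
  expect_true(all(feedforward_match(m, s$bank) == 0))
})

test_that("memoryless state equals the drive; leaky state converges geometrically", {
  s <- mstd_setup(mt_grid = 16, bank_grid = 4)
  drive <- matrix(runif(16), 4, 4)
  st <- mstd_state(s$bank, lambda = 1, inhibition = 0)
  st <- recurrent_step(st, drive)
  expect_identical(st$activity, drive)

  st <- mstd_state(s$bank, lambda = 0.2, inhibition = 0)
  for (k in 1:10) {
    st <- recurrent_step(st, drive)
    expect_equal(max(abs(st$activity - drive)),
                 max(drive) * (1 - 0.2)^k, tolerance = 1e-9)
  }
  expect_error(mstd_state(s$bank, lambda = 0), "lambda")
  expect_error(mstd_state(s$bank, lambda = 1.2), "lambda")
  expect_error(recurrent_step(st, -drive), "non-negative")
})

test_that("decoding picks the argmax and breaks ties row-major", {
  s <- mstd_setup(mt_grid = 16, bank_grid = 4)
  st <- mstd_state(s$bank, lambda = 1, inhibition = 0)
  a <- matrix(0, 4, 4); a[2, 3] <- 1
  st <- recurrent_step(st, a)
  est <- decode_heading(st)
  expect_equal(est$azimuth, s$bank$az[3])
  expect_equal(est$elevation, s$bank$el[2])
  expect_equal(est$margin, 1)
  # tie: (1, 4) has row-major index 4, (2, 1) has 5 -> (1, 4) wins
  a2 <- matrix(0, 4, 4); a2[1, 4] <- 1; a2[2, 1] <- 1
  st2 <- recurrent_step(mstd_state(s$bank, lambda = 1, inhibition = 0), a2)
  est2 <- decode_heading(st2)
  expect_equal(c(est2$row, est2$col), c(1, 4))
  expect_equal(est2$margin, 0)
  # all-zero state has no heading signal
  st0 <- mstd_state(s$bank)
  expect_error(decode_heading(st0), "no heading signal")
})

test_that("center template decodes to the image center", {
  cfg <- mt_config(grid = 16, n_directions = 8, n_speeds = 7)
  bank <- template_bank(64, cfg)
  st <- mstd_state(bank, lambda = 1, inhibition = 0)
  a <- matrix(0, 64, 64); a[32, 32] <- 1
  st <- recurrent_step(st, a)
  est <- decode_heading(st)
  half_step <- 90 / 64 / 2
  expect_lte(abs(est$azimuth), half_step + 1e-12)
  expect_lte(abs(est$elevation), half_step + 1e-12)
})

test_that("lower leak rates never shorten convergence after a heading jump", {
  s <- mstd_setup(mt_grid = 16, bank_grid = 4)
  d_old <- matrix(0, 4, 4); d_old[1, 1] <- 1
  d_new <- matrix(0, 4, 4); d_new[4, 4] <- 1
  frames_to_switch <- function(lambda) {
    st <- mstd_state(s$bank, lambda = lambda, inhibition = 0)
    for (k in 1:40) st <- recurrent_step(st, d_old)
    for (k in 1:200) {
      st <- recurrent_step(st, d_new)
      if (decode_heading(st)$row == 4) return(k)
    }
    Inf
  }
  laten <- vapply(c(0.5, 0.2, 0.1), frames_to_switch, numeric(1))
  expect_true(all(diff(laten) >= 0))
  expect_gt(laten[3], 1)
})
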