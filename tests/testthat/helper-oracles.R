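# Independent oracles used across test files. Each reimplements the checked
# quantity by a different route (dense-grid search, closed form, explicit
# double loops) and must stay free of the package's own code paths.

# Brute-force quantile of a histogram: forward-evaluate the integral of the
# piecewise-constant density at 1e5 grid points and scan for the first one
# reaching `level` (vs the package's inverse interpolation of the CDF).
dense_quantile_oracle <- function(dist, level, n_grid = 1e5) {
  edges <- dist$bin_edges
  widths <- diff(edges)
  dens <- dist$bin_mass / widths
  cum <- c(0, cumsum(dist$bin_mass))
  s <- seq(edges[1], edges[length(edges)], length.out = n_grid)
  bin <- findInterval(s, edges, all.inside = TRUE)
  cdf <- cum[bin] + (s - edges[bin]) * dens[bin]
  s[which(cdf >= level - 1e-12)[1]]
}

# Random non-degenerate histogram for property-style tests.
random_speed_distribution <- function(bins = NULL) {
  if (is.null(bins)) bins <- sample(8:64, 1)
  hi <- runif(1, 0.5, 60)
  mass <- rgamma(bins, shape = runif(1, 0.2, 3))
  speed_distribution(seq(0, hi, length.out = bins + 1), mass / sum(mass),
                     n_samples = 1000L)
}

# Explicit per-template, per-direction template match with rectified cosine
# weights (the definition, evaluated literally). The template's preferred
# direction at a pixel is the exact motion-field direction for translation
# toward the template's FoE: the pixel-space radial vector from the FoE
# pixel, scaled per axis by the gnomonic Jacobian f / (f^2 + coord^2).
brute_force_drive <- function(m_signal, bank) {
  cfg <- bank$config
  g <- cfg$grid
  pa <- deseflow:::pixel_angles(g, cfg$fov_deg)
  f <- pa$focal_px
  x <- as.vector(matrix(pa$x, g, g, byrow = TRUE))
  y <- as.vector(matrix(pa$y_up, g, g))
  theta <- deseflow:::mt_preferred_directions(cfg)
  drive <- matrix(0, bank$grid, bank$grid)
  for (i in seq_len(bank$grid)) {
    for (j in seq_len(bank$grid)) {
      xf <- f * tan(bank$az[j] * pi / 180)
      yf <- f * tan(bank$el[i] * pi / 180)
      dx <- (x - xf) * f / (f^2 + x^2)
      dy <- (y - yf) * f / (f^2 + y^2)
      phi <- atan2(dy, dx)
      dead <- dx == 0 & dy == 0
      tot <- 0
      for (d in seq_along(theta)) {
        w <- pmax(cos(theta[d] - phi), 0)
        w[dead] <- 0
        tot <- tot + sum(m_signal[, d] * w)
      }
      drive[i, j] <- tot
    }
  }
  drive
}

# Closed-form reprojection flow for a frontoparallel wall at world z = z0
# seen by two identity-orientation cameras: the wall point behind pixel
# (x, y) of the first camera is p1 + (z0 - p1z) * (x/f, y/f, 1).
wall_flow_oracle <- function(grid, fov_deg, z0, p1, p2) {
  f <- (grid / 2) / tan(fov_deg * pi / 360)
  u <- v <- matrix(0, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      x <- (j - 0.5) - grid / 2
      y <- grid / 2 - (i - 0.5)
      px <- p1[1] + (z0 - p1[3]) * x / f
      py <- p1[2] + (z0 - p1[3]) * y / f
      az0 <- atan(x / f)
      el0 <- atan(y / f)
      az1 <- atan((px - p2[1]) / (z0 - p2[3]))
      el1 <- atan((py - p2[2]) / (z0 - p2[3]))
      u[i, j] <- (az1 - az0) * 180 / pi
      v[i, j] <- (el1 - el0) * 180 / pi
    }
  }
  list(u = u, v = v)
}

# Noiseless radial flow toward an (az, el) heading: pure translation
# against a frontoparallel wall, rendered by reprojection.
radial_flow <- function(az_deg, el_deg, grid, fov_deg = 90, speed = 0.5,
                        z0 = 30) {
  d <- c(tan(az_deg * pi / 180), tan(el_deg * pi / 180), 1)
  d <- d / sqrt(sum(d^2))
  sc <- depth_scene("frontoparallel_wall", wall_distance = z0)
  render_flow(sc,
              camera_pose(c(0, 0, 0), grid = grid, fov_deg = fov_deg),
              camera_pose(speed * d, grid = grid, fov_deg = fov_deg))
}

# A small cluttered-scene flow sample for encoding tests.
sample_flow <- function(grid = 24, seed = 7, frame = 1) {
  sc <- depth_scene("cluttered", seed = seed)
  tr <- make_trajectory(seed, grid = grid, scene = sc)
  fr <- tr$frames
  pos <- rbind(fr$pos_x, fr$pos_y, fr$pos_z)
  render_flow(sc,
              camera_pose(pos[, frame], grid = grid, fov_deg = tr$fov_deg),
              camera_pose(pos[, frame + 1], grid = grid,
                          fov_deg = tr$fov_deg))
}
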