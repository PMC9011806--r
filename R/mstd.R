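#' Bank of radial-expansion heading templates
#'
#' A `grid x grid` (default 64 x 64) bank of MSTd-like template cells. Each
#' template prefers, at every pixel, the unit direction pointing away from
#' its own focus-of-expansion position — evaluated as the exact,
#' depth-independent motion-field direction for translation toward that
#' FoE (radial in pixel coordinates, mapped into the angular coordinates
#' flow is measured in). Template FoE positions sit at the cell centers of
#' a uniform partition of the field of view, so adjacent template headings
#' differ by `fov / grid` degrees (about 1.41 degrees at the defaults).
#'
#' The template match is speed-agnostic: MT activity is summed over speed
#' channels and weighted by the rectified cosine between each direction
#' channel's preferred direction and the template's preferred direction at
#' that pixel — heading information is carried by flow vector directions,
#' not magnitudes.
#'
#' @param grid Templates per side. Default 64.
#' @param config The [mt_config()] whose responses this bank will match
#'   (supplies the pixel grid, direction channels and field of view).
#' @return An object of class `template_bank`.
#' @export
template_bank <- function(grid = 64L, config = mt_config()) {
  stopifnot(inherits(config, "mt_config"))
  grid <- as.integer(grid)
  if (grid < 2L) stop("bank grid must be >= 2")
  fov <- config$fov_deg
  step <- fov / grid
  structure(
    list(grid = grid, fov_deg = fov, step_deg = step,
         az = -fov / 2 + (seq_len(grid) - 0.5) * step,     # per column
         el = fov / 2 - (seq_len(grid) - 0.5) * step,      # per row
         config = config,
         cache = new.env(parent = emptyenv())),
    class = "template_bank"
  )
}

#' Angular spacing of a template bank
#'
#' @param bank A [template_bank()].
#' @return Degrees of visual angle between adjacent template headings.
#' @export
bank_resolution_deg <- function(bank) {
  stopifnot(inherits(bank, "template_bank"))
  bank$step_deg
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf(
    "template_bank: %dx%d radial templates over %g deg FOV (%.3f deg spacing)\n",
    x$grid, x$grid, x$fov_deg, x$step_deg))
  invisible(x)
}

# The rectified-cosine template match decomposes over half-circle direction
# sets: relu(cos(theta_d - phi)) is cos(theta_d)cos(phi) +
# sin(theta_d)sin(phi) summed over the directions in the half circle around
# phi, and that active set is piecewise constant in phi on bins of width
# (direction spacing)/2 anchored at 90 degrees. These matrices map the
# direction-marginal MT signal onto per-bin cosine/sine sums.
halfset_matrices <- function(config) {
  d <- config$n_directions
  theta <- mt_preferred_directions(config)
  k2 <- 2L * d
  width <- 2 * pi / k2
  mid <- pi / 2 + (seq_len(k2) - 0.5) * width
  act <- outer(theta, mid, function(a, b) cos(a - b) > 0)
  list(CW = act * cos(theta), SW = act * sin(theta), k2 = k2)
}

# Per-template pixel geometry for a chunk of templates (column-major
# template order): half-set bin of the radial direction phi, plus cos(phi)
# and sin(phi). Zero radius (pixel at the template FoE) contributes nothing.
#
# Pure-translation flow radiates from the FoE along straight lines in PIXEL
# coordinates; in the per-axis angular coordinates the flow is measured in,
# that direction is the pixel-space radial vector scaled per axis by the
# gnomonic Jacobian d(az)/dx = f / (f^2 + x^2) (and likewise in y). Using
# that exact, depth-independent motion-field direction keeps templates
# aligned with noiseless radial flow at all eccentricities.
template_chunk_geometry <- function(bank, templates) {
  cfg <- bank$config
  g <- cfg$grid
  pa <- pixel_angles(g, cfg$fov_deg)
  f <- pa$focal_px
  x_p <- as.vector(matrix(pa$x, g, g, byrow = TRUE))   # per column
  y_p <- as.vector(matrix(pa$y_up, g, g))              # per row
  jx <- f / (f^2 + x_p^2)
  jy <- f / (f^2 + y_p^2)
  p <- length(x_p)
  rows <- ((templates - 1L) %% bank$grid) + 1L
  cols <- ((templates - 1L) %/% bank$grid) + 1L
  k2 <- 2L * cfg$n_directions
  width_deg <- 360 / k2
  n <- length(templates)
  lin <- matrix(0L, p, n)
  cphi <- matrix(0, p, n)
  sphi <- matrix(0, p, n)
  for (i in seq_len(n)) {
    x_f <- f * tan(bank$az[cols[i]] * pi / 180)
    y_f <- f * tan(bank$el[rows[i]] * pi / 180)
    dx <- jx * (x_p - x_f)
    dy <- jy * (y_p - y_f)
    r <- sqrt(dx^2 + dy^2)
    nz <- r > 0
    phi_deg <- atan2(dy, dx) * 180 / pi
    k <- as.integer(floor(((phi_deg - 90) %% 360) / width_deg)) + 1L
    k[k > k2] <- k2
    lin[, i] <- (k - 1L) * p + seq_len(p)
    cphi[nz, i] <- dx[nz] / r[nz]
    sphi[nz, i] <- dy[nz] / r[nz]
  }
  list(lin = lin, cphi = cphi, sphi = sphi)
}

# cache geometry when the problem is small enough to keep resident
bank_geometry <- function(bank, templates, chunk_key) {
  p <- bank$config$grid^2
  total <- as.numeric(p) * bank$grid^2
  if (total > 2e7) return(template_chunk_geometry(bank, templates))
  if (is.null(bank$cache[[chunk_key]]))
    bank$cache[[chunk_key]] <- template_chunk_geometry(bank, templates)
  bank$cache[[chunk_key]]
}

#' Feedforward template match
#'
#' Computes each template's drive: the sum over pixels and direction
#' channels of MT activity (summed over speed channels) weighted by the
#' rectified cosine between the channel's preferred direction and the
#' template's radial direction at that pixel.
#'
#' @param mt An `mt_response` from [mt_respond()], or the
#'   `grid^2 x n_directions` matrix from [mt_direction_signal()].
#' @param bank A [template_bank()] built for the same [mt_config()].
#' @return A `grid x grid` matrix of non-negative template drives.
#' @export
feedforward_match <- function(mt, bank) {
  stopifnot(inherits(bank, "template_bank"))
  cfg <- bank$config
  if (inherits(mt, "mt_response")) {
    if (mt$config$fov_deg != cfg$fov_deg || mt$config$grid != cfg$grid ||
        mt$config$n_directions != cfg$n_directions)
      stop("MT response and template bank configurations do not match")
    m <- apply(mt$activity, c(1, 2, 3), sum)
    m <- matrix(m, cfg$grid^2, cfg$n_directions)
  } else {
    m <- as.matrix(mt)
    if (nrow(m) != cfg$grid^2 || ncol(m) != cfg$n_directions)
      stop("direction signal dimensions do not match the bank's MT config")
  }
  hs <- halfset_matrices(cfg)
  a <- m %*% hs$CW
  b <- m %*% hs$SW
  n_t <- bank$grid^2
  drive <- numeric(n_t)
  chunk <- max(1L, min(n_t, as.integer(2e6 / nrow(m))))
  starts <- seq(1L, n_t, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n_t)
    geo <- bank_geometry(bank, idx, sprintf("g%d", s))
    av <- matrix(a[geo$lin], nrow(geo$lin), ncol(geo$lin))
    bv <- matrix(b[geo$lin], nrow(geo$lin), ncol(geo$lin))
    drive[idx] <- colSums(geo$cphi * av + geo$sphi * bv)
  }
  drive[drive < 0] <- 0   # guard tiny negative rounding
  matrix(drive, bank$grid, bank$grid)
}

#' Recurrent MSTd state
#'
#' Leaky-integrator activity over the template grid with global subtractive
#' competition:
#' `a(t+1) = (1 - lambda) a(t) + lambda * max(drive - inhibition * mean(a(t)), 0)`.
#' With `lambda = 1` and zero inhibition the state equals the instantaneous
#' feedforward drive (memoryless limit). This is a deliberately simplified
#' stand-in for fully recurrent competitive dynamics; `lambda` sets the
#' convergence latency after a heading jump. The default 0.05 is calibrated
#' so that the decode takes about 14 frames to switch after an abrupt jump
#' between equal-strength drives, in the 10-20 frame latency range of
#' interest.
#'
#' @param bank The [template_bank()] whose drive this state integrates.
#' @param lambda Leak rate in `(0, 1]`. Default 0.05.
#' @param inhibition Global competition strength (>= 0). Default 1.
#' @return An object of class `mstd_state`.
#' @export
mstd_state <- function(bank, lambda = 0.05, inhibition = 1) {
  stopifnot(inherits(bank, "template_bank"))
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1)
    stop("lambda must lie in (0, 1]")
  if (inhibition < 0) stop("inhibition must be non-negative")
  structure(
    list(activity = matrix(0, bank$grid, bank$grid), lambda = lambda,
         inhibition = inhibition, frame = 0L,
         az = bank$az, el = bank$el, step_deg = bank$step_deg),
    class = "mstd_state"
  )
}

#' One recurrent update of the MSTd state
#'
#' @param state An [mstd_state()].
#' @param drive Non-negative drive matrix from [feedforward_match()].
#' @return The updated `mstd_state`.
#' @export
recurrent_step <- function(state, drive) {
  stopifnot(inherits(state, "mstd_state"))
  drive <- as.matrix(drive)
  if (!all(dim(drive) == dim(state$activity)))
    stop("drive dimensions do not match the state grid")
  if (any(drive < 0)) stop("drive must be non-negative")
  inh <- state$inhibition * mean(state$activity)
  state$activity <- (1 - state$lambda) * state$activity +
    state$lambda * pmax(drive - inh, 0)
  state$frame <- state$frame + 1L
  state
}

#' Decode heading from MSTd activity
#'
#' The heading estimate is the heading preference of the maximally active
#' template; ties break deterministically to the lowest row-major index.
#'
#' @param state An [mstd_state()] with at least one positive entry.
#' @return An object of class `heading_estimate`: list with `azimuth`,
#'   `elevation` (degrees), `row`, `col`, and `margin` (winner minus
#'   runner-up activity).
#' @export
decode_heading <- function(state) {
  stopifnot(inherits(state, "mstd_state"))
  a <- state$activity
  mx <- max(a)
  if (mx <= 0) stop("no heading signal")
  hits <- which(a == mx, arr.ind = TRUE)
  rm_index <- (hits[, 1] - 1L) * ncol(a) + hits[, 2]
  pick <- which.min(rm_index)
  row <- hits[pick, 1]; col <- hits[pick, 2]
  runner <- if (length(a) > 1L) max(a[-((col - 1L) * nrow(a) + row)]) else 0
  structure(
    list(azimuth = state$az[col], elevation = state$el[row],
         row = unname(row), col = unname(col), margin = mx - runner),
    class = "heading_estimate"
  )
}

#' @export
print.heading_estimate <- function(x, ...) {
  cat(sprintf("heading_estimate: az %.2f deg, el %.2f deg (margin %.3g)\n",
              x$azimuth, x$elevation, x$margin))
  invisible(x)
}
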