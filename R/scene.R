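#' Parametric depth scenes
#'
#' Scenes supply, for every viewing ray, the distance to the nearest
#' surface. Three kinds are available:
#'
#' * `ground_plane` — an infinite horizontal plane at world height 0. Rays
#'   above the horizon miss the scene ("sky") and are marked invalid.
#'   Self-motion over it produces a smooth speed gradient (fast below, slow
#'   near the horizon).
#' * `frontoparallel_wall` — a vertical plane a fixed distance ahead along
#'   the world z axis; approach produces a narrow band of flow speeds.
#' * `cluttered` — a seeded random range field: log-distance is bilinearly
#'   interpolated from a coarse grid over world viewing direction
#'   (azimuth wrap-around), clamped to `depth_range`, combined with a
#'   ground-plane floor. It stands in for scenes with naturalistic depth
#'   variation (buildings, trees, shelving) without modelling geometry.
#'
#' World coordinates are right-handed with +y up; the default camera looks
#' along +z.
#'
#' @param kind One of `"ground_plane"`, `"frontoparallel_wall"`,
#'   `"cluttered"`.
#' @param wall_distance Wall position on the world z axis (meters), for
#'   `frontoparallel_wall`. Default 50.
#' @param depth_range Range (meters) of the cluttered random field.
#'   Default `c(4, 200)`.
#' @param roughness_grid Resolution of the cluttered field's coarse grid
#'   (cells per 360 degrees of azimuth). Default 24; larger is rougher.
#' @param seed Seed for the cluttered field. Default 1.
#' @return An object of class `depth_scene`.
#' @export
depth_scene <- function(kind = c("ground_plane", "frontoparallel_wall",
                                 "cluttered"),
                        wall_distance = 50, depth_range = c(4, 200),
                        roughness_grid = 24L, seed = 1L) {
  kind <- match.arg(kind)
  sc <- list(kind = kind, wall_distance = wall_distance,
             depth_range = depth_range)
  if (kind == "frontoparallel_wall" && wall_distance <= 0)
    stop("wall_distance must be positive")
  if (kind == "cluttered") {
    if (depth_range[1] <= 0 || depth_range[2] <= depth_range[1])
      stop("depth_range must be positive and increasing")
    k <- as.integer(roughness_grid)
    # coarse log-range field over (world azimuth, world elevation)
    sc$field <- with_seed(seed, matrix(
      stats::runif(k * (k %/% 2 + 1L), log(depth_range[1]),
                   log(depth_range[2])),
      nrow = k %/% 2 + 1L, ncol = k))
    sc$field_k <- k
  }
  structure(sc, class = "depth_scene")
}

#' @export
print.depth_scene <- function(x, ...) {
  cat("depth_scene:", x$kind)
  if (x$kind == "frontoparallel_wall")
    cat(sprintf(" (z = %g m)", x$wall_distance))
  if (x$kind == "cluttered")
    cat(sprintf(" (range %g-%g m + ground)", x$depth_range[1],
                x$depth_range[2]))
  cat("\n")
  invisible(x)
}

# Evaluate `expr` under a private seeded RNG stream, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Distance along world rays to the scene surface
#'
#' @param scene A [depth_scene()].
#' @param position Camera position, world 3-vector (meters, +y up).
#' @param dirs 3 x n matrix of unit world ray directions.
#' @return Length-n vector of ray distances (meters); `Inf` where the ray
#'   misses the scene (sky).
#' @export
scene_range <- function(scene, position, dirs) {
  stopifnot(inherits(scene, "depth_scene"))
  n <- ncol(dirs)
  t_ground <- rep(Inf, n)
  down <- dirs[2, ] < -1e-9
  t_ground[down] <- -position[2] / dirs[2, down]

  if (scene$kind == "ground_plane") return(t_ground)

  if (scene$kind == "frontoparallel_wall") {
    tw <- rep(Inf, n)
    fwd <- dirs[3, ] > 1e-9
    tw[fwd] <- (scene$wall_distance - position[3]) / dirs[3, fwd]
    tw[tw <= 0] <- Inf
    return(tw)
  }

  # cluttered: random range field over viewing direction + ground floor
  az <- atan2(dirs[1, ], dirs[3, ])                  # [-pi, pi]
  el <- asin(pmin(pmax(dirs[2, ], -1), 1))           # [-pi/2, pi/2]
  t_field <- exp(bilinear_wrap(scene$field, az, el, scene$field_k))
  pmin(t_field, t_ground)
}

# Bilinear interpolation on a (k/2+1) x k grid over (elevation, azimuth)
# with azimuth wrap-around.
bilinear_wrap <- function(field, az, el, k) {
  nr <- nrow(field)
  gx <- (az + pi) / (2 * pi) * k                     # [0, k], wraps
  gy <- (el + pi / 2) / pi * (nr - 1L)               # [0, nr-1]
  x0 <- floor(gx); fx <- gx - x0
  y0 <- floor(gy); fy <- gy - y0
  y0 <- pmin(pmax(y0, 0), nr - 2L); fy <- pmin(pmax(gy - y0, 0), 1)
  i0 <- (x0 %% k) + 1L; i1 <- ((x0 + 1L) %% k) + 1L
  j0 <- y0 + 1L; j1 <- y0 + 2L
  f00 <- field[cbind(j0, i0)]; f01 <- field[cbind(j0, i1)]
  f10 <- field[cbind(j1, i0)]; f11 <- field[cbind(j1, i1)]
  (1 - fy) * ((1 - fx) * f00 + fx * f01) + fy * ((1 - fx) * f10 + fx * f11)
}

#' Camera pose
#'
#' Pinhole camera with a square pixel grid and 90 x 90 degree field of view
#' by default. Camera axes: +x right, +y up, +z forward (the optical axis);
#' `orientation` is the camera-to-world rotation.
#'
#' @param position World position (meters).
#' @param orientation 3x3 camera-to-world rotation matrix. Default identity
#'   (looking along world +z).
#' @param grid Pixels per side. Default 256.
#' @param fov_deg Field of view (degrees). Default 90.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(position, orientation = diag(3), grid = 256L,
                        fov_deg = 90) {
  position <- as.numeric(position)
  if (length(position) != 3L) stop("position must be a 3-vector")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-8 ||
      det(orientation) < 0)
    stop("orientation must be a proper rotation matrix")
  structure(list(position = position, orientation = orientation,
                 grid = as.integer(grid), fov_deg = fov_deg),
            class = "camera_pose")
}

# Unit ray directions in camera coordinates for every pixel, as a 3 x n
# matrix in column-major pixel order (row index fastest).
camera_rays <- function(grid, fov_deg) {
  ang <- pixel_angles(grid, fov_deg)
  f <- ang$focal_px
  x <- matrix(ang$x, grid, grid, byrow = TRUE)     # per column
  y <- matrix(ang$y_up, grid, grid)                # per row
  d <- rbind(as.vector(x), as.vector(y), f)
  d / rep(sqrt(colSums(d^2)), each = 3)
}

# Image-plane angular coordinates (degrees) of camera-frame directions.
camera_angles <- function(dirs) {
  list(az = atan2(dirs[1, ], dirs[3, ]) * 180 / pi,
       el = atan2(dirs[2, ], dirs[3, ]) * 180 / pi)
}
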