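#' Render ground-truth optic flow between two camera poses
#'
#' Reprojection flow: every pixel of the first pose is back-projected
#' through the scene's depth along its viewing ray to a 3-D point, the
#' point is re-projected under the second pose, and the flow is the
#' difference of the angular image coordinates, in degrees/frame. Camera
#' rotation between the poses is handled by the same reprojection. Pixels
#' whose ray misses the scene (sky) or whose point falls behind the second
#' camera are marked invalid and carry zero flow.
#'
#' The ground-truth heading stored on the result is the image-plane
#' direction of the translation `pose_t1$position - pose_t$position`,
#' expressed in the first camera's frame.
#'
#' @param scene A [depth_scene()].
#' @param pose_t,pose_t1 [camera_pose()]s at consecutive frames, sharing
#'   grid and field of view.
#' @return A [flow_field()] in degrees/frame.
#' @export
render_flow <- function(scene, pose_t, pose_t1) {
  stopifnot(inherits(pose_t, "camera_pose"), inherits(pose_t1, "camera_pose"))
  if (pose_t$grid != pose_t1$grid || pose_t$fov_deg != pose_t1$fov_deg)
    stop("poses must share grid and field of view")
  g <- pose_t$grid
  rays <- camera_rays(g, pose_t$fov_deg)          # camera frame, 3 x n
  w <- pose_t$orientation %*% rays                # world frame
  rng <- scene_range(scene, pose_t$position, w)
  hit <- is.finite(rng) & rng > 0

  u <- v <- numeric(ncol(rays))
  valid <- hit
  if (any(hit)) {
    pts <- pose_t$position + w[, hit, drop = FALSE] *
      rep(rng[hit], each = 3)                     # world points
    rel <- pts - pose_t1$position
    cam1 <- crossprod(pose_t1$orientation, rel)   # second camera frame
    front <- cam1[3, ] > 1e-12
    a0 <- camera_angles(rays[, hit, drop = FALSE])
    a1 <- camera_angles(cam1)
    du <- a1$az - a0$az
    dv <- a1$el - a0$el
    du[!front] <- 0; dv[!front] <- 0
    idx <- which(hit)
    u[idx] <- du; v[idx] <- dv
    valid[idx] <- front
  }

  t_world <- pose_t1$position - pose_t$position
  t_cam <- as.vector(crossprod(pose_t$orientation, t_world))
  heading <- if (t_cam[3] > 0) {
    c(atan2(t_cam[1], t_cam[3]), atan2(t_cam[2], t_cam[3])) * 180 / pi
  } else NULL

  flow_field(matrix(u, g, g), matrix(v, g, g), matrix(valid, g, g),
             heading = heading, fov_deg = pose_t$fov_deg)
}

#' Render the flow sequence of a whole trajectory
#'
#' Applies [render_flow()] to every consecutive pose pair of a
#' [make_trajectory()] result, yielding one flow field per trajectory
#' frame.
#'
#' @param scene A [depth_scene()].
#' @param trajectory A [make_trajectory()] result.
#' @param grid Flow grid resolution; defaults to the trajectory's grid.
#' @return List of [flow_field()]s, one per frame.
#' @export
render_trajectory_flow <- function(scene, trajectory, grid = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  g <- if (is.null(grid)) trajectory$grid else as.integer(grid)
  fr <- trajectory$frames
  n <- nrow(fr)
  pos <- rbind(fr$pos_x, fr$pos_y, fr$pos_z)
  pos <- cbind(pos, trajectory$end_position)
  lapply(seq_len(n), function(t) {
    render_flow(scene,
                camera_pose(pos[, t], grid = g,
                            fov_deg = trajectory$fov_deg),
                camera_pose(pos[, t + 1L], grid = g,
                            fov_deg = trajectory$fov_deg))
  })
}

#' Add estimation noise to a flow field
#'
#' Mimics the error profile of pixel-based flow estimation: every pixel's
#' (u, v) receives i.i.d. zero-mean Gaussian noise of standard deviation
#' `sigma`, and invalid ("sky") pixels — where real estimators latch onto
#' low-contrast junk — additionally receive large outlier vectors at rate
#' `sky_outlier_rate` (component standard deviation `outlier_sigma`).
#' After noising, every pixel carries a measurement, so the returned field
#' is fully valid.
#'
#' @param flow A [flow_field()].
#' @param sigma Noise standard deviation (degrees/frame).
#' @param sky_outlier_rate Probability that a sky pixel becomes an outlier.
#' @param seed Integer seed; the same seed reproduces the same field.
#' @param outlier_sigma Outlier component scale. Default `10 * sigma`
#'   (or 0.5 degrees/frame when `sigma = 0`).
#' @return A [flow_field()].
#' @export
add_estimation_noise <- function(flow, sigma, sky_outlier_rate = 0.02,
                                 seed = 1L, outlier_sigma = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sky_outlier_rate < 0 || sky_outlier_rate > 1)
    stop("sky_outlier_rate must lie in [0, 1]")
  if (sigma == 0 && sky_outlier_rate == 0) return(flow)
  if (is.null(outlier_sigma))
    outlier_sigma <- if (sigma > 0) 10 * sigma else 0.5
  with_seed(seed, {
    n <- length(flow$u)
    u <- flow$u + matrix(stats::rnorm(n, 0, sigma), nrow(flow$u))
    v <- flow$v + matrix(stats::rnorm(n, 0, sigma), nrow(flow$v))
    sky <- which(!flow$valid)
    if (length(sky) > 0 && sky_outlier_rate > 0) {
      out <- sky[stats::runif(length(sky)) < sky_outlier_rate]
      u[out] <- u[out] + stats::rnorm(length(out), 0, outlier_sigma)
      v[out] <- v[out] + stats::rnorm(length(out), 0, outlier_sigma)
    }
    flow_field(u, v, valid = NULL, heading = flow$heading,
               fov_deg = flow$fov_deg)
  })
}
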