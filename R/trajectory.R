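#' Seeded multi-segment camera trajectory
#'
#' Generates the stimulus protocol used throughout the experiments: five
#' connected linear translation segments of 30 frames each, separated by
#' 3-frame transitions, for a total of 162 frames. Each segment's heading
#' is chosen by sampling a random pixel in the camera image (uniformly over
#' the full image) and translating toward it; segment speed is sampled
#' uniformly from 1-20 m/s and the starting camera height from 1-5 m.
#' During a transition both the heading pixel and the speed are linearly
#' interpolated (three interim headings) between the adjacent segments.
#'
#' The camera orientation is held fixed (looking along world +z) for the
#' whole trial, so the focus of expansion sits at the sampled heading pixel
#' and jumps across segments; see the methods vignette for why the camera
#' is not re-aimed at each new heading.
#'
#' When a `scene` is supplied, trajectories whose camera path comes within
#' `clearance` meters of scene geometry (the ground, or the wall) are
#' rejected and re-sampled from an offset seed, an automated stand-in for
#' manual review of collision-free stimuli.
#'
#' @param seed Integer seed; the same seed always yields the same
#'   trajectory.
#' @param grid Image grid used for heading-pixel sampling. Default 256.
#' @param fov_deg Field of view (degrees). Default 90.
#' @param n_segments Number of linear segments. Default 5.
#' @param segment_frames Frames per segment. Default 30.
#' @param transition_frames Frames per transition. Default 3.
#' @param speed_range Segment speed range (m/s), within `[1, 20]`.
#' @param height_range Start height range (m), within `[1, 5]`.
#' @param fps Frame rate (frames/second). Default 30.
#' @param scene Optional [depth_scene()] used for collision rejection.
#' @param clearance Minimum camera-to-geometry distance (m). Default 0.5.
#' @param max_attempts Resampling attempts before giving up. Default 1000.
#' @return An object of class `trajectory`: a list with a per-frame data
#'   frame `frames` (columns `frame`, `segment`, `is_transition`, `speed`,
#'   `heading_az`, `heading_el`, `dir_x/y/z`, `pos_x/y/z`), the extra final
#'   position `end_position`, and the protocol parameters.
#' @export
make_trajectory <- function(seed, grid = 256L, fov_deg = 90,
                            n_segments = 5L, segment_frames = 30L,
                            transition_frames = 3L,
                            speed_range = c(1, 20),
                            height_range = c(1, 5), fps = 30,
                            scene = NULL, clearance = 0.5,
                            max_attempts = 1000L) {
  if (speed_range[1] < 1 || speed_range[2] > 20 ||
      speed_range[1] > speed_range[2])
    stop("speed_range must lie within [1, 20] m/s")
  if (height_range[1] < 1 || height_range[2] > 5 ||
      height_range[1] > height_range[2])
    stop("height_range must lie within [1, 5] m")
  if (n_segments < 2L) stop("need at least two segments")

  for (attempt in seq_len(max_attempts)) {
    tr <- with_seed(seed + (attempt - 1L),
                    sample_trajectory(grid, fov_deg, n_segments,
                                      segment_frames, transition_frames,
                                      speed_range, height_range, fps))
    tr$seed <- seed
    tr$attempts <- attempt
    if (is.null(scene) || trajectory_clear(tr, scene, clearance)) return(tr)
  }
  stop("no collision-free trajectory found after ", max_attempts,
       " attempts")
}

# One unvalidated draw of the protocol.
sample_trajectory <- function(grid, fov_deg, n_segments, segment_frames,
                              transition_frames, speed_range, height_range,
                              fps) {
  f <- (grid / 2) / tan(fov_deg * pi / 360)
  px <- stats::runif(n_segments, 0, grid)
  py <- stats::runif(n_segments, 0, grid)
  speeds <- stats::runif(n_segments, speed_range[1], speed_range[2])
  height <- stats::runif(1, height_range[1], height_range[2])

  # per-frame heading pixel and speed schedule
  hp_x <- hp_y <- sp <- seg <- numeric(0)
  trans <- logical(0)
  for (k in seq_len(n_segments)) {
    hp_x <- c(hp_x, rep(px[k], segment_frames))
    hp_y <- c(hp_y, rep(py[k], segment_frames))
    sp <- c(sp, rep(speeds[k], segment_frames))
    seg <- c(seg, rep(k, segment_frames))
    trans <- c(trans, rep(FALSE, segment_frames))
    if (k < n_segments) {
      w <- seq_len(transition_frames) / (transition_frames + 1)
      hp_x <- c(hp_x, (1 - w) * px[k] + w * px[k + 1])
      hp_y <- c(hp_y, (1 - w) * py[k] + w * py[k + 1])
      sp <- c(sp, (1 - w) * speeds[k] + w * speeds[k + 1])
      seg <- c(seg, rep(k + 1L, transition_frames))
      trans <- c(trans, rep(TRUE, transition_frames))
    }
  }
  n_frames <- length(sp)

  # heading pixel -> camera/world direction (orientation fixed = identity)
  x <- hp_x - grid / 2
  y_up <- grid / 2 - hp_y
  d <- rbind(x, y_up, f)
  d <- d / rep(sqrt(colSums(d^2)), each = 3)

  # integrate positions; per-frame displacement = speed / fps
  step <- d * rep(sp / fps, each = 3)
  pos <- matrix(0, 3, n_frames + 1L)
  pos[2, 1] <- height
  cum <- if (n_frames == 1L) matrix(step, 3, 1) else t(apply(step, 1, cumsum))
  pos[, -1] <- pos[, 1] + cum

  ang <- camera_angles(d)
  frames <- data.frame(
    frame = seq_len(n_frames), segment = seg, is_transition = trans,
    speed = sp, heading_az = ang$az, heading_el = ang$el,
    dir_x = d[1, ], dir_y = d[2, ], dir_z = d[3, ],
    pos_x = pos[1, seq_len(n_frames)], pos_y = pos[2, seq_len(n_frames)],
    pos_z = pos[3, seq_len(n_frames)]
  )
  structure(
    list(frames = frames, end_position = pos[, n_frames + 1L],
         grid = grid, fov_deg = fov_deg, fps = fps,
         start_height = height, n_segments = n_segments,
         segment_frames = segment_frames,
         transition_frames = transition_frames),
    class = "trajectory"
  )
}

# TRUE when every camera position keeps `clearance` meters from geometry.
trajectory_clear <- function(tr, scene, clearance) {
  pos <- rbind(t(as.matrix(tr$frames[, c("pos_x", "pos_y", "pos_z")])),
               deparse.level = 0)
  pos <- cbind(pos, tr$end_position)
  heights <- pos[2, ]
  ok <- TRUE
  if (scene$kind %in% c("ground_plane", "cluttered"))
    ok <- ok && all(heights > clearance)
  if (scene$kind == "frontoparallel_wall")
    ok <- ok && all(scene$wall_distance - pos[3, ] > clearance)
  ok
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames (%d segments x %d + %d x %d transitions), start height %.2f m\n",
    nrow(x$frames), x$n_segments, x$segment_frames,
    x$n_segments - 1L, x$transition_frames, x$start_height))
  invisible(x)
}

#' Write a trajectory's ground-truth heading track as CSV
#'
#' Columns: `frame`, `azimuth_deg`, `elevation_deg`, `segment_index`,
#' `is_transition`.
#'
#' @param trajectory A [make_trajectory()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_heading_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(
    frame = trajectory$frames$frame,
    azimuth_deg = trajectory$frames$heading_az,
    elevation_deg = trajectory$frames$heading_el,
    segment_index = trajectory$frames$segment,
    is_transition = trajectory$frames$is_transition
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth heading track CSV
#'
#' @param path File written by [write_heading_csv()].
#' @return A data frame.
#' @export
read_heading_csv <- function(path) {
  utils::read.csv(path)
}
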