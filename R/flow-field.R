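#' Dense optic-flow field
#'
#' A grid of image-motion vectors in degrees/frame, with a validity mask and
#' the ground-truth heading (image-plane direction of the camera's
#' translation) when known.
#'
#' Conventions used throughout the package: pixels are indexed `(row, col)`
#' with row 1 at the top; angular image coordinates are centered at the
#' image center with azimuth positive rightward and elevation positive
#' upward; a pixel at horizontal offset x from the center (in pixels) has
#' azimuth `atan(x / f)` under the exact pinhole mapping with focal length
#' `f = (grid/2) / tan(fov/2)`. `u` is the azimuthal and `v` the elevational
#' displacement per frame, in degrees.
#'
#' @param u,v Numeric matrices of equal dimension (degrees/frame).
#' @param valid Logical matrix marking pixels with a defined measurement;
#'   defaults to all `TRUE`.
#' @param heading Optional ground truth `c(azimuth, elevation)` in degrees.
#' @param fov_deg Field of view in degrees (square). Default 90.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(u, v, valid = NULL, heading = NULL, fov_deg = 90) {
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == dim(v))) stop("u and v must share dimensions")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  valid <- as.matrix(valid)
  if (!all(dim(valid) == dim(u))) stop("valid mask must share dimensions")
  if (any(!is.finite(u[valid])) || any(!is.finite(v[valid])))
    stop("flow must be finite on the valid mask")
  u[!valid] <- 0; v[!valid] <- 0
  structure(list(u = u, v = v, valid = valid, heading = heading,
                 fov_deg = fov_deg),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  m <- sqrt(x$u^2 + x$v^2)
  cat(sprintf(
    "flow_field: %dx%d, %.1f%% valid, speeds [%.3g, %.3g] deg/frame\n",
    nrow(x$u), ncol(x$u), 100 * mean(x$valid),
    min(m[x$valid]), max(m[x$valid])))
  if (!is.null(x$heading))
    cat(sprintf("  heading: az %.2f deg, el %.2f deg\n",
                x$heading[1], x$heading[2]))
  invisible(x)
}

#' Flow vector magnitudes
#'
#' @param flow A [flow_field()].
#' @return Matrix of speeds (degrees/frame); zero at invalid pixels.
#' @export
flow_speed <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  sqrt(flow$u^2 + flow$v^2)
}

# Angular image coordinates (degrees) of every pixel center for a square
# grid with the given field of view. Cached per (grid, fov).
pixel_angles <- local({
  cache <- new.env(parent = emptyenv())
  function(grid, fov_deg) {
    key <- sprintf("%d_%g", grid, fov_deg)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- (grid / 2) / tan(fov_deg * pi / 360)
    x <- (seq_len(grid) - 0.5) - grid / 2           # rightward, per column
    y_up <- grid / 2 - (seq_len(grid) - 0.5)        # upward, per row
    az <- atan(x / f) * 180 / pi
    el <- atan(y_up / f) * 180 / pi
    res <- list(
      az = matrix(az, grid, grid, byrow = TRUE),    # varies along columns
      el = matrix(el, grid, grid),                  # varies along rows
      focal_px = f, x = x, y_up = y_up
    )
    cache[[key]] <- res
    res
  }
})
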