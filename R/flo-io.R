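#' Write a flow field as a Middlebury .flo file
#'
#' Exact Middlebury layout: little-endian float32 magic `202021.25`, int32
#' width, int32 height, then row-major interleaved float32 `(u, v)` pairs.
#' Flow is stored in pixels/frame; the degrees-per-pixel conversion factor
#' (field of view / grid width) and the ground-truth heading are recorded
#' in a JSON sidecar `<path>.json` so the field can be read back in
#' degrees/frame.
#'
#' @param flow A [flow_field()] (degrees/frame).
#' @param path Output path (conventionally ending in `.flo`).
#' @param sidecar Write the JSON sidecar. Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_flo <- function(flow, path, sidecar = TRUE) {
  stopifnot(inherits(flow, "flow_field"))
  dpp <- flow$fov_deg / ncol(flow$u)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(202021.25, con, size = 4L, endian = "little")
  writeBin(c(ncol(flow$u), nrow(flow$u)), con, size = 4L, endian = "little")
  u_px <- t(flow$u) / dpp   # row-major flattening: x fastest
  v_px <- t(flow$v) / dpp
  inter <- as.numeric(rbind(as.vector(u_px), as.vector(v_px)))
  writeBin(inter, con, size = 4L, endian = "little")
  if (sidecar) {
    meta <- list(deg_per_pixel = dpp, fov_deg = flow$fov_deg,
                 heading = flow$heading,
                 invalid = which(!flow$valid))
    writeLines(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a Middlebury .flo file
#'
#' Validates the magic number and payload length, reporting the file name
#' and byte offset on malformed input. When the JSON sidecar written by
#' [write_flo()] is present the field is converted back to degrees/frame
#' and the validity mask and heading restored; otherwise supply
#' `deg_per_pixel` (use 1 to keep pixel units).
#'
#' @param path Path to the `.flo` file.
#' @param deg_per_pixel Conversion factor when no sidecar exists.
#' @return A [flow_field()].
#' @export
read_flo <- function(path, deg_per_pixel = NULL) {
  size <- file.info(path)$size
  if (is.na(size) || size < 12L)
    stop(sprintf("%s: truncated .flo header (%s bytes, need 12)",
                 path, ifelse(is.na(size), "missing", size)))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, numeric(), n = 1L, size = 4L, endian = "little")
  if (!isTRUE(abs(magic - 202021.25) < 1e-3))
    stop(sprintf("%s: bad .flo magic %g at byte 0 (expected 202021.25)",
                 path, magic))
  wh <- readBin(con, integer(), n = 2L, size = 4L, endian = "little")
  w <- wh[1]; h <- wh[2]
  if (w < 1L || h < 1L)
    stop(sprintf("%s: invalid dimensions %dx%d at byte 4", path, w, h))
  need <- as.numeric(w) * h * 2
  if (size - 12L < need * 4)
    stop(sprintf("%s: truncated payload at byte %d (%d floats expected)",
                 path, 12L + as.integer(size - 12L), as.integer(need)))
  dat <- readBin(con, numeric(), n = need, size = 4L, endian = "little")

  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (is.null(deg_per_pixel) && file.exists(sidecar))
    meta <- jsonlite::fromJSON(sidecar)
  dpp <- if (!is.null(meta)) meta$deg_per_pixel
         else if (!is.null(deg_per_pixel)) deg_per_pixel
         else stop(sprintf("%s: no sidecar found; supply deg_per_pixel",
                           path))
  u_px <- matrix(dat[seq(1, length(dat), by = 2)], h, w, byrow = TRUE)
  v_px <- matrix(dat[seq(2, length(dat), by = 2)], h, w, byrow = TRUE)
  valid <- matrix(TRUE, h, w)
  heading <- NULL
  fov <- dpp * w
  if (!is.null(meta)) {
    if (length(meta$invalid) > 0) valid[meta$invalid] <- FALSE
    if (!is.null(meta$heading)) heading <- meta$heading
    if (!is.null(meta$fov_deg)) fov <- meta$fov_deg
  }
  flow_field(u_px * dpp, v_px * dpp, valid, heading = heading,
             fov_deg = fov)
}
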