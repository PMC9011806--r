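#' Rolling time horizon over recent flow frames
#'
#' A first-in-first-out buffer of the speed samples from the most recent
#' `horizon_frames` flow fields. The pooled distribution over the buffer
#' weights every stored vector equally, regardless of which frame it came
#' from; it defines the stimulus distribution for dynamic tuning. The
#' object is environment-backed so that [update_horizon()] mutates it in
#' place, as a streaming accumulator should.
#'
#' @param horizon_frames Window length in frames (>= 1).
#' @param bins Histogram bins used when pooling. Default 128.
#' @return An object of class `rolling_horizon`.
#' @export
rolling_horizon <- function(horizon_frames, bins = 128L) {
  horizon_frames <- as.integer(horizon_frames)
  if (is.na(horizon_frames) || horizon_frames < 1L)
    stop("horizon_frames must be >= 1")
  e <- new.env(parent = emptyenv())
  e$horizon_frames <- horizon_frames
  e$bins <- as.integer(bins)
  e$buffer <- list()  # per-frame magnitude vectors, oldest first
  class(e) <- "rolling_horizon"
  e
}

#' Push a frame into a rolling horizon and return the pooled distribution
#'
#' Evicts the oldest frame once the buffer holds `horizon_frames` entries,
#' then pools all buffered speed samples (equal per-vector weight) into a
#' fresh [speed_distribution()]. Before the buffer first fills the pool is
#' over however many frames exist.
#'
#' @param h A [rolling_horizon()].
#' @param frame A [flow_field()] or numeric vector of speed magnitudes.
#' @return The pooled [speed_distribution()].
#' @export
update_horizon <- function(h, frame) {
  stopifnot(inherits(h, "rolling_horizon"))
  mags <- pool_flow_magnitudes(frame)
  if (length(mags) == 0L) stop("no flow data")
  if (length(h$buffer) >= h$horizon_frames)
    h$buffer <- h$buffer[-1L]
  h$buffer[[length(h$buffer) + 1L]] <- mags
  horizon_distribution(h)
}

#' Pooled distribution of a rolling horizon
#'
#' @param h A [rolling_horizon()] holding at least one frame.
#' @return The pooled [speed_distribution()].
#' @export
horizon_distribution <- function(h) {
  stopifnot(inherits(h, "rolling_horizon"))
  if (length(h$buffer) == 0L) stop("no flow data")
  speed_histogram(unlist(h$buffer, use.names = FALSE), h$bins)
}

#' @export
print.rolling_horizon <- function(x, ...) {
  cat(sprintf("rolling_horizon: %d/%d frames buffered (%d bins)\n",
              length(x$buffer), x$horizon_frames, x$bins))
  invisible(x)
}
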