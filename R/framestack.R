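#' Fluorescence frame stack
#'
#' One channel's movie: a rows x cols x frames intensity array with frame
#' timestamps (seconds, strictly increasing) and the pixel pitch (mm/px).
#' Intensities may be integer camera counts or floating-point values.
#'
#' @param data Numeric or integer array `rows x cols x frames` (a matrix is
#'   accepted as a single frame).
#' @param times Frame timestamps in seconds, strictly increasing, one per
#'   frame.
#' @param pixel_pitch Pixel pitch in mm/pixel.
#' @param channel Optional channel name (e.g. "cfp", "vm").
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(data, times, pixel_pitch = 0.1, channel = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    format_error("frame stack data must be a rows x cols x frames array")
  if (length(times) != dim(data)[3])
    format_error(sprintf("got %d timestamps for %d frames",
                         length(times), dim(data)[3]))
  if (length(times) > 1 && any(diff(times) <= 0))
    format_error("frame timestamps must be strictly increasing")
  if (pixel_pitch <= 0) config_error("pixel_pitch must be positive")
  structure(list(data = data, times = as.numeric(times),
                 pixel_pitch = pixel_pitch, channel = channel),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack%s: %d x %d px, %d frames, t = [%g, %g] s, %g mm/px\n",
              if (is.null(x$channel)) "" else paste0(" [", x$channel, "]"),
              d[1], d[2], d[3], min(x$times), max(x$times), x$pixel_pitch))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

# Extract the T x P trace matrix for the given pixel (linear) indices.
stack_traces <- function(stack, idx) {
  d <- dim(stack$data)
  m <- matrix(stack$data, d[1] * d[2], d[3])
  t(m[idx, , drop = FALSE]) * 1.0
}

# Frame-wise mean over a pixel index set.
stack_roi_mean <- function(stack, idx) {
  d <- dim(stack$data)
  m <- matrix(stack$data, d[1] * d[2], d[3])
  colMeans(m[idx, , drop = FALSE])
}
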