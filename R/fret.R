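#' Paired CFP/YFP recording
#'
#' Bundles the donor (CFP) and acceptor (YFP) frame stacks with the binary
#' heart mask. Both stacks must share shape, timestamps and pixel pitch.
#'
#' @param cfp,yfp [frame_stack()]s of equal geometry and timing.
#' @param mask Logical matrix marking epicardial pixels.
#' @return A `fret_recording` object.
#' @export
fret_recording <- function(cfp, yfp, mask) {
  stopifnot(inherits(cfp, "frame_stack"), inherits(yfp, "frame_stack"))
  if (!identical(dim(cfp$data), dim(yfp$data)))
    format_error("CFP and YFP stacks must share shape")
  if (!isTRUE(all.equal(cfp$times, yfp$times)))
    format_error("CFP and YFP stacks must share timestamps")
  if (cfp$pixel_pitch != yfp$pixel_pitch)
    format_error("CFP and YFP stacks must share pixel pitch")
  if (!is.logical(mask) || !all(dim(mask) == dim(cfp$data)[1:2]))
    format_error("mask must be a logical rows x cols matrix matching the stacks")
  structure(list(cfp = cfp, yfp = yfp, mask = mask),
            class = "fret_recording")
}

#' Register the split acceptor image onto the donor image
#'
#' The dual-emission image splitter projects CFP and YFP side by side onto
#' one detector; residual translation between the two half-images is found
#' by exhaustive search of integer shifts maximizing the normalized
#' cross-correlation of the time-averaged frames. Ties are broken by the
#' smallest `|dy| + |dx|`, then by row-major order over `(dy, dx)`.
#'
#' @param cfp,yfp [frame_stack()]s of the same shape.
#' @param max_shift Maximum absolute shift searched, in pixels.
#' @return A list: `shift = c(dy, dx)` such that `yfp[i + dy, j + dx]`
#'   corresponds to `cfp[i, j]`, and `yfp`, the aligned stack (edge pixels
#'   with no source data become `NA`).
#' @export
register_split <- function(cfp, yfp, max_shift = 5) {
  stopifnot(inherits(cfp, "frame_stack"), inherits(yfp, "frame_stack"))
  if (!identical(dim(cfp$data)[1:2], dim(yfp$data)[1:2]))
    format_error("stacks must share frame shape")
  if (max_shift < 0) config_error("max_shift must be >= 0")
  A <- apply(cfp$data, c(1, 2), mean)
  B <- apply(yfp$data, c(1, 2), mean)
  if (all(A == 0) || all(B == 0))
    analysis_error("registration failed: all-zero image")
  rows <- nrow(A); cols <- ncol(A)
  shifts <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  shifts <- shifts[order(shifts$dy, shifts$dx), c("dy", "dx")]
  best <- NULL
  for (s in seq_len(nrow(shifts))) {
    dy <- shifts$dy[s]; dx <- shifts$dx[s]
    ri <- max(1, 1 - dy):min(rows, rows - dy)
    ci <- max(1, 1 - dx):min(cols, cols - dx)
    if (!length(ri) || !length(ci)) next
    a <- as.vector(A[ri, ci]); b <- as.vector(B[ri + dy, ci + dx])
    if (sd(a) == 0 || sd(b) == 0) next
    cc <- stats::cor(a, b)
    cand <- list(cc = cc, dy = dy, dx = dx, l1 = abs(dy) + abs(dx))
    if (is.null(best) || cc > best$cc + 1e-12 ||
        (abs(cc - best$cc) <= 1e-12 && cand$l1 < best$l1))
      best <- cand
  }
  if (is.null(best)) analysis_error("registration failed: no valid overlap")
  aligned <- array(NA_real_, dim = dim(yfp$data))
  ri <- max(1, 1 - best$dy):min(rows, rows - best$dy)
  ci <- max(1, 1 - best$dx):min(cols, cols - best$dx)
  aligned[ri, ci, ] <- yfp$data[ri + best$dy, ci + best$dx, , drop = FALSE]
  list(shift = c(dy = best$dy, dx = best$dx),
       yfp = frame_stack(aligned, yfp$times, yfp$pixel_pitch, yfp$channel))
}

#' Pixel-wise FRET ratio and normalized dFRET movie
#'
#' Computes the FRET ratio R = CFP/YFP per pixel per frame, the per-pixel
#' baseline ratio R0 as the mean of R over the pre-stimulus
#' `baseline_window`, and dFRET = R/R0, which normalizes away static gain
#' differences and uneven illumination. Pixels whose minimum YFP count is
#' at or below `yfp_floor` are removed from the mask to avoid ratio blow-up
#' at dark pixels.
#'
#' @param rec A [fret_recording()].
#' @param baseline_window Integer frame indices (1-based) of the baseline
#'   period, e.g. `1:3`.
#' @param yfp_floor Minimum acceptable YFP count after offset subtraction
#'   (default 0; a practical choice is 5 x the camera offset).
#' @param dark_offset Camera dark offset in counts, subtracted from both
#'   channels before the ratio: length 1 or a vector `c(cfp, yfp)`. An
#'   unsubtracted offset compresses the ratio toward 1.
#' @return A `ratio_movie`: arrays `r` and `delta` (NA outside the mask),
#'   matrix `r0`, the pruned `mask`, `times`, `baseline_window`,
#'   `pixel_pitch`.
#' @export
compute_ratio <- function(rec, baseline_window, yfp_floor = 0,
                          dark_offset = 0) {
  stopifnot(inherits(rec, "fret_recording"))
  nf <- n_frames(rec$cfp)
  baseline_window <- as.integer(baseline_window)
  if (!length(baseline_window) || any(baseline_window < 1) ||
      any(baseline_window > nf))
    config_error("baseline_window must be nonempty frame indices within range")
  mask <- rec$mask
  if (!any(mask)) analysis_error("mask is empty")
  dark_offset <- rep_len(as.numeric(dark_offset), 2)
  cfp <- rec$cfp$data - dark_offset[1]
  yfp <- rec$yfp$data - dark_offset[2]
  yfp_min <- apply(yfp, c(1, 2), min)
  mask <- mask & (yfp_min > yfp_floor)
  if (!any(mask))
    analysis_error("no pixels remain after applying the YFP floor")
  r <- (cfp * 1.0) / (yfp * 1.0)
  nas <- array(rep(!mask, nf), dim = dim(r))
  r[nas] <- NA_real_
  r0 <- apply(r[, , baseline_window, drop = FALSE], c(1, 2), mean)
  delta <- r / array(rep(r0, nf), dim = dim(r))
  structure(list(r = r, r0 = r0, delta = delta, mask = mask,
                 times = rec$cfp$times, baseline_window = baseline_window,
                 pixel_pitch = rec$cfp$pixel_pitch),
            class = "ratio_movie")
}

#' ROI dFRET time course with response metrics
#'
#' Averages the per-pixel dFRET movie over an ROI (ratio first, then
#' spatial averaging) and attaches the bolus-response metrics from
#' [response_metrics()].
#'
#' @param movie A [compute_ratio()] result.
#' @param roi Logical matrix or linear pixel indices defining the ROI.
#' @param label ROI name.
#' @param min_response Passed to [response_metrics()].
#' @return A `delta_fret_trace`: `roi_label`, `times` (s), `values`
#'   (dimensionless dFRET), `baseline_window`, `max_ratio`, `time_to_peak`,
#'   `decay_t50`.
#' @export
roi_trace <- function(movie, roi, label = "ROI", min_response = 0.01) {
  stopifnot(inherits(movie, "ratio_movie"))
  if (is.logical(roi)) roi <- which(roi)
  roi <- intersect(as.integer(roi), which(movie$mask))
  if (!length(roi))
    analysis_error(sprintf("ROI '%s' does not intersect the mask", label))
  nf <- length(movie$times)
  flat <- matrix(movie$delta, ncol = nf)
  values <- colMeans(flat[roi, , drop = FALSE])
  tr <- structure(list(roi_label = label, times = movie$times,
                       values = values,
                       baseline_window = movie$baseline_window,
                       max_ratio = NA_real_, time_to_peak = NA_real_,
                       decay_t50 = NA_real_),
                  class = "delta_fret_trace")
  if (nf >= 3 && nf > max(movie$baseline_window)) {
    m <- response_metrics(tr, movie$baseline_window, min_response)
    tr$max_ratio <- unname(m["max_ratio"])
    tr$time_to_peak <- unname(m["time_to_peak"])
    tr$decay_t50 <- unname(m["decay_t50"])
  }
  tr
}

#' Bolus-response metrics of a dFRET trace
#'
#' `max_ratio` (Max R/R0) is the maximum dFRET after the baseline window;
#' `time_to_peak` its (earliest) timestamp; `decay_t50` the time from the
#' peak to the first post-peak crossing (linearly interpolated between
#' frames) of the level halfway between the peak and baseline (1), i.e.
#' `1 + (max_ratio - 1)/2`. When the trace never rises more than
#' `min_response` above baseline the metrics are undefined (`NA`), not an
#' error.
#'
#' @param trace A `delta_fret_trace` (or list with `times` and `values`).
#' @param baseline_window Integer frame indices of the baseline period.
#' @param min_response Minimum response amplitude above 1 for metrics to be
#'   defined.
#' @return Named numeric vector `c(max_ratio, time_to_peak, decay_t50)`.
#' @export
response_metrics <- function(trace, baseline_window = trace$baseline_window,
                             min_response = 0.01) {
  times <- trace$times; values <- trace$values
  baseline_window <- as.integer(baseline_window)
  post <- seq_along(values) > max(baseline_window)
  if (length(values) < 3 || sum(post) < 1)
    analysis_error("trace needs at least 3 frames in and after the baseline window")
  und <- c(max_ratio = NA_real_, time_to_peak = NA_real_,
           decay_t50 = NA_real_)
  pv <- values[post]; pt <- times[post]
  max_ratio <- max(pv)
  if (!is.finite(max_ratio) || max_ratio <= 1 + min_response) return(und)
  pk <- which(pv == max_ratio)[1]
  time_to_peak <- pt[pk]
  half <- 1 + (max_ratio - 1) / 2
  decay_t50 <- NA_real_
  if (pk < length(pv)) {
    below <- which(pv[(pk + 1):length(pv)] <= half)
    if (length(below)) {
      j <- pk + below[1]          # first index at/below the half level
      t1 <- pt[j - 1]; t2 <- pt[j]; v1 <- pv[j - 1]; v2 <- pv[j]
      tcross <- if (v1 == v2) t2 else t1 + (v1 - half) / (v1 - v2) * (t2 - t1)
      decay_t50 <- tcross - time_to_peak
    }
  }
  c(max_ratio = max_ratio, time_to_peak = time_to_peak,
    decay_t50 = decay_t50)
}

#' Cross-sectional profile of a map
#'
#' Samples a per-pixel map along the segment from `p_start` to `p_end` at
#' 1-pixel steps, averaging perpendicular to the segment over `width`
#' pixels (bilinear interpolation; samples outside the grid or on `NA`
#' pixels are dropped from the perpendicular average).
#'
#' @param map Numeric matrix (e.g. one FRET frame or an R0 map).
#' @param p_start,p_end `c(row, col)` endpoints (1-based, inside the grid).
#' @param width Perpendicular averaging width in pixels (odd widths center
#'   the band on the segment).
#' @param pixel_pitch mm per pixel for the distance axis.
#' @return data.frame with `distance_mm` and `value`.
#' @export
line_profile <- function(map, p_start, p_end, width = 1, pixel_pitch = 0.1) {
  stopifnot(is.matrix(map))
  inside <- function(p) all(p >= 1) && p[1] <= nrow(map) && p[2] <= ncol(map)
  if (!inside(p_start) || !inside(p_end))
    config_error("profile endpoints must lie inside the grid")
  d <- sqrt(sum((p_end - p_start)^2))
  if (d == 0) analysis_error("zero-length profile segment")
  u <- (p_end - p_start) / d           # unit vector along the segment
  v <- c(-u[2], u[1])                  # unit perpendicular
  steps <- seq(0, d, by = 1)
  offs <- seq_len(width) - (width + 1) / 2
  vals <- vapply(steps, function(s) {
    p <- p_start + s * u
    mean(vapply(offs, function(o)
      bilinear_at(map, p[1] + o * v[1], p[2] + o * v[2]),
      numeric(1)), na.rm = TRUE)
  }, numeric(1))
  data.frame(distance_mm = steps * pixel_pitch, value = vals)
}

bilinear_at <- function(map, r, c) {
  if (r < 1 || c < 1 || r > nrow(map) || c > ncol(map)) return(NA_real_)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nrow(map)); c1 <- min(c0 + 1, ncol(map))
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * map[r0, c0] + (1 - fr) * fc * map[r0, c1] +
    fr * (1 - fc) * map[r1, c0] + fr * fc * map[r1, c1]
}
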