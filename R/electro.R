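#' Optical trace
#'
#' A uniformly sampled fluorescence time series from one pixel or ROI, with
#' the polarity of the deflection on activation (+1 if fluorescence rises
#' on depolarization, -1 if it falls, as for RH237-like voltage dyes).
#'
#' @param times Sample times in ms, uniformly spaced.
#' @param values Fluorescence values (arbitrary units).
#' @param polarity +1 or -1.
#' @param source Optional pixel coordinate or ROI label.
#' @return An `optical_trace` object.
#' @export
optical_trace <- function(times, values, polarity = 1, source = NULL) {
  if (length(times) != length(values) || length(times) < 2)
    format_error("times and values must be equal length (>= 2)")
  dts <- diff(times)
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1]))
    format_error("optical traces must be uniformly sampled")
  if (!polarity %in% c(-1, 1)) config_error("polarity must be +1 or -1")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 polarity = polarity, source = source),
            class = "optical_trace")
}

trace_dt <- function(trace) trace$times[2] - trace$times[1]

#' @rdname optical_trace
#' @param trace An `optical_trace`.
#' @return `normalize_polarity()`: the trace with values flipped so that
#'   upstrokes are positive and `polarity = +1`.
#' @export
normalize_polarity <- function(trace) {
  stopifnot(inherits(trace, "optical_trace"))
  if (trace$polarity == 1) return(trace)
  trace$values <- -trace$values
  trace$polarity <- 1
  trace
}

#' 3 x 3 spatial Gaussian filter
#'
#' Per-frame convolution with a normalized 3 x 3 Gaussian kernel
#' (sigma = 1 px), using symmetric (edge-replicating) borders. The exact
#' kernel is `gaussian_kernel3()`: outer product of
#' `c(exp(-0.5), 1, exp(-0.5))` with itself, normalized to sum 1.
#'
#' @param stack A [frame_stack()] (or a single matrix).
#' @return The filtered stack (or matrix).
#' @export
spatial_filter <- function(stack) {
  mat_in <- is.matrix(stack)
  x <- if (mat_in) array(stack, dim = c(dim(stack), 1L)) else {
    stopifnot(inherits(stack, "frame_stack"))
    stack$data * 1.0
  }
  k <- gaussian_kernel3()
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2) format_error("frames must be at least 2 x 2")
  pad <- x[c(1, seq_len(d[1]), d[1]), c(1, seq_len(d[2]), d[2]), ,
           drop = FALSE]
  out <- array(0, dim = d)
  for (a in 1:3) for (b in 1:3)
    out <- out + k[a, b] * pad[a:(a + d[1] - 1), b:(b + d[2] - 1), ,
                               drop = FALSE]
  if (mat_in) return(out[, , 1])
  frame_stack(out, stack$times, stack$pixel_pitch, stack$channel)
}

#' @rdname spatial_filter
#' @export
gaussian_kernel3 <- function() {
  k1 <- c(exp(-0.5), 1, exp(-0.5))
  k <- outer(k1, k1)
  k / sum(k)
}

#' Top-hat baseline drift correction
#'
#' Subtracts the morphological opening (erosion then dilation with a flat
#' structuring element of `window_ms`) of the polarity-normalized trace.
#' The opening tracks the diastolic lower envelope — including slow drift —
#' while ignoring deflections narrower than the window, so the corrected
#' trace has a baseline near zero. The window must exceed the longest beat
#' period; 1.5 x the median beat interval is a good default.
#'
#' @param trace An [optical_trace()].
#' @param window_ms Structuring element length in ms (>= 3 samples).
#' @return The corrected, polarity-normalized trace.
#' @export
baseline_correct <- function(trace, window_ms) {
  stopifnot(inherits(trace, "optical_trace"))
  trace <- normalize_polarity(trace)
  w <- round(window_ms / trace_dt(trace))
  if (w < 3) config_error("top-hat window must span at least 3 samples")
  opened <- as.vector(morph_open_cols(matrix(trace$values), as.integer(w)))
  trace$values <- trace$values - opened
  trace
}

#' Detect beats in an optical trace
#'
#' Beats are located at peaks of the forward-difference derivative above an
#' adaptive threshold (`threshold_frac` times the maximum derivative),
#' separated by at least `min_separation_ms`. The trace should be
#' polarity-normalized and baseline-corrected first. Heart rate is
#' 60000 / mean inter-activation interval (ms) when at least two beats are
#' found.
#'
#' @param trace An [optical_trace()].
#' @param min_separation_ms Minimum separation between beats in ms.
#' @param threshold_frac Fraction of the maximum derivative used as the
#'   detection threshold.
#' @return A `beat_set`: `activation_times` (ms), `activation_idx` (sample
#'   indices), `heart_rate` (bpm, NA with < 2 beats), `n_beats`. Empty
#'   (zero beats) for flat traces, never an error.
#' @export
detect_beats <- function(trace, min_separation_ms = 50,
                         threshold_frac = 0.5) {
  stopifnot(inherits(trace, "optical_trace"))
  dt <- trace_dt(trace)
  d <- diff(trace$values)
  empty <- structure(list(activation_times = numeric(0),
                          activation_idx = integer(0),
                          heart_rate = NA_real_, n_beats = 0L),
                     class = "beat_set")
  if (!length(d) || max(d) <= 0) return(empty)
  thr <- threshold_frac * max(d)
  cand <- which(d >= thr)
  if (!length(cand)) return(empty)
  min_sep <- max(1L, round(min_separation_ms / dt))
  picked <- integer(0)
  for (i in cand[order(-d[cand], cand)]) {
    if (!length(picked) || all(abs(picked - i) >= min_sep))
      picked <- c(picked, i)
  }
  picked <- sort(picked)
  at <- trace$times[picked]
  hr <- if (length(picked) >= 2) 60000 / mean(diff(at)) else NA_real_
  structure(list(activation_times = at, activation_idx = picked,
                 heart_rate = hr, n_beats = length(picked)),
            class = "beat_set")
}

#' Activation time within a beat window
#'
#' The activation time is the timestamp of the maximum forward-difference
#' derivative within the window (the steepest upstroke sample); ties go to
#' the earliest sample. Optional parabolic refinement interpolates the
#' derivative peak to sub-sample resolution.
#'
#' @param trace A polarity-normalized [optical_trace()].
#' @param beat_window Integer sample index range (e.g. `120:300`) containing
#'   one upstroke.
#' @param refine Parabolic sub-sample refinement (default off).
#' @return Activation time in ms, or `NA` if the maximum derivative is not
#'   positive.
#' @export
activation_time <- function(trace, beat_window, refine = FALSE) {
  stopifnot(inherits(trace, "optical_trace"))
  w <- as.integer(beat_window)
  w <- w[w >= 1 & w <= length(trace$values)]
  if (length(w) < 2) analysis_error("beat window too short")
  x <- trace$values
  d <- x[w[-1]] - x[w[-length(w)]]
  if (max(d) <= 0) return(NA_real_)
  # earliest tie; differences within a relative 1e-9 of the maximum tie
  # (a linear upstroke has a flat derivative up to floating-point jitter)
  k <- which(d >= max(d) * (1 - 1e-9))[1]
  tk <- trace$times[w[k]]
  if (refine && k > 1 && k < length(d)) {
    dm <- d[k - 1]; d0 <- d[k]; dp <- d[k + 1]
    den <- dm - 2 * d0 + dp
    if (den < 0) tk <- tk + trace_dt(trace) * 0.5 * (dm - dp) / den
  }
  tk
}

#' Action potential / calcium transient duration for one beat
#'
#' Duration from the activation time (maximum upstroke derivative) to the
#' first post-peak crossing, linearly interpolated between samples, of
#' `peak - level * amplitude`, where the amplitude is the peak minus the
#' diastolic baseline (mean of `baseline_pre_ms` preceding the upstroke).
#' `apd(level = 0.8)` gives APD80; `catd(level = 0.5)` gives CaTD50.
#'
#' @param trace A polarity-normalized, baseline-corrected [optical_trace()].
#' @param beat_window Integer sample index range covering the beat (from
#'   just before the upstroke to just before the next).
#' @param level Repolarization/decay fraction (0.8 for APD80, 0.5 for
#'   CaTD50).
#' @param baseline_pre_ms Diastolic baseline window before the upstroke, ms.
#' @param hold_ms The threshold crossing is accepted only when the trace
#'   stays at or below the threshold for this long (rejects single-sample
#'   noise excursions; default 3 ms).
#' @param refine_activation Refine the activation sample by the partial
#'   forward difference preceding the first maximal one, which equals the
#'   sub-sample onset fraction of a linear upstroke (default TRUE; durations
#'   are then referenced to the refined onset).
#' @return Duration in ms, or `NA` when activation or the threshold
#'   recrossing is undefined within the window.
#' @export
apd <- function(trace, beat_window, level = 0.8, baseline_pre_ms = 10,
                hold_ms = 3, refine_activation = TRUE) {
  stopifnot(inherits(trace, "optical_trace"))
  w <- as.integer(beat_window)
  w <- w[w >= 1 & w <= length(trace$values)]
  if (length(w) < 3) analysis_error("beat window too short")
  dt <- trace_dt(trace)
  res <- beat_durations_cols(matrix(trace$values),
                             as.integer(min(w) - 1L),
                             as.integer(max(w)),
                             level,
                             as.integer(round(baseline_pre_ms / dt)),
                             dt,
                             as.integer(max(1, round(hold_ms / dt))),
                             isTRUE(refine_activation))
  res$durations[1, 1]
}

#' @rdname apd
#' @export
catd <- function(trace, beat_window, level = 0.5, baseline_pre_ms = 10,
                 hold_ms = 3, refine_activation = TRUE) {
  apd(trace, beat_window, level = level, baseline_pre_ms = baseline_pre_ms,
      hold_ms = hold_ms, refine_activation = refine_activation)
}

# Shared per-burst preparation: filter, extract mask traces, polarity,
# reference-trace beat detection, top-hat correction, beat windows.
electro_prep <- function(stack, mask, polarity, filter = TRUE,
                         min_separation_ms = 50, tophat_ms = NULL,
                         pre_ms = 40) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.logical(mask) || !all(dim(mask) == dim(stack$data)[1:2]))
    format_error("mask must be a logical matrix matching the stack")
  if (!any(mask)) analysis_error("mask is empty")
  if (filter) stack <- spatial_filter(stack)
  times_ms <- (stack$times - stack$times[1]) * 1000
  dt <- times_ms[2] - times_ms[1]
  mask_idx <- which(mask)
  traces <- stack_traces(stack, mask_idx) * polarity

  ref_raw <- optical_trace(times_ms, rowMeans(traces))
  beats0 <- detect_beats(ref_raw, min_separation_ms)
  if (beats0$n_beats < 1) analysis_error("no beats detected in the recording")
  interval <- if (beats0$n_beats >= 2)
    stats::median(diff(beats0$activation_times)) else
      length(times_ms) * dt / 2
  if (is.null(tophat_ms)) tophat_ms <- 1.5 * interval

  w <- as.integer(max(3, round(tophat_ms / dt)))
  traces <- traces - morph_open_cols(traces, w)
  ref <- optical_trace(times_ms, rowMeans(traces))
  beats <- detect_beats(ref, min_separation_ms)
  if (beats$n_beats < 1) analysis_error("no beats detected after correction")

  pre <- round(pre_ms / dt)
  starts <- pmax(1L, beats$activation_idx - pre)
  ends <- c(starts[-1],
            min(length(times_ms),
                beats$activation_idx[beats$n_beats] + round(interval / dt)))
  complete <- ends > starts + 2 & ends <= length(times_ms)
  list(traces = traces, mask_idx = mask_idx, dt = dt, beats = beats,
       win_start = starts[complete], win_end = ends[complete],
       interval = interval, dim = dim(stack$data)[1:2])
}

#' Per-pixel duration map over consecutive beats
#'
#' Runs the full trace pipeline on every mask pixel of a burst stack —
#' 3 x 3 Gaussian spatial filter, polarity normalization, top-hat baseline
#' correction, beat segmentation from the mask-mean reference trace — then
#' measures APD80 (`kind = "apd80"`) or CaTD50 (`kind = "catd50"`) per beat
#' and averages the first `n_beats` complete beats per pixel (all available
#' when fewer).
#'
#' @param stack A Vm or Ca burst [frame_stack()].
#' @param mask Logical epicardial mask.
#' @param kind `"apd80"` or `"catd50"`.
#' @param n_beats Number of consecutive beats to average (default 10).
#' @param polarity Deflection polarity; defaults to -1 for `"apd80"` (Vm)
#'   and +1 for `"catd50"` (Ca).
#' @param filter Apply the spatial filter (default TRUE).
#' @param min_separation_ms,tophat_ms,pre_ms,baseline_pre_ms Trace-pipeline
#'   tuning: beat separation, top-hat window (default 1.5 x median beat
#'   interval), beat-window margin before activation, diastolic baseline
#'   span.
#' @param hold_ms,refine_activation Crossing/activation handling as in
#'   [apd()].
#' @return A `duration_map`: `kind`, `values` (ms matrix, NA outside mask
#'   or where undefined), `n_beats_averaged`, `level`, `heart_rate` (bpm
#'   from the reference trace), `mask`.
#' @export
duration_map <- function(stack, mask, kind = c("apd80", "catd50"),
                         n_beats = 10, polarity = NULL, filter = TRUE,
                         min_separation_ms = 50, tophat_ms = NULL,
                         pre_ms = 40, baseline_pre_ms = 10, hold_ms = 3,
                         refine_activation = TRUE) {
  kind <- match.arg(kind)
  level <- if (kind == "apd80") 0.8 else 0.5
  if (is.null(polarity)) polarity <- if (kind == "apd80") -1 else 1
  prep <- electro_prep(stack, mask, polarity, filter,
                       min_separation_ms, tophat_ms, pre_ms)
  nb <- length(prep$win_start)
  if (nb < 1) analysis_error("no complete beats available")
  use <- seq_len(min(n_beats, nb))
  res <- beat_durations_cols(prep$traces,
                             as.integer(prep$win_start[use] - 1L),
                             as.integer(prep$win_end[use]),
                             level,
                             as.integer(round(baseline_pre_ms / prep$dt)),
                             prep$dt,
                             as.integer(max(1, round(hold_ms / prep$dt))),
                             isTRUE(refine_activation))
  durs <- res$durations
  vals <- colMeans(durs, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  out <- matrix(NA_real_, prep$dim[1], prep$dim[2])
  out[prep$mask_idx] <- vals
  structure(list(kind = kind, values = out,
                 n_beats_averaged = length(use), level = level,
                 heart_rate = prep$beats$heart_rate, mask = mask),
            class = "duration_map")
}

#' Activation map for one beat
#'
#' Per-pixel activation time (maximum upstroke derivative) within the
#' chosen beat, expressed relative to the earliest pixel; the earliest site
#' identifies the leading pacemaker in atrial preparations.
#'
#' @inheritParams duration_map
#' @param beat_index Which beat to map (1-based among complete beats).
#' @param polarity Deflection polarity (default -1, Vm).
#' @return An `activation_map`: `values` (ms matrix relative to the
#'   earliest pixel), `earliest_site` `c(row, col)` (row-major first among
#'   ties), `beat_index`, `mask`.
#' @export
activation_map <- function(stack, mask, beat_index = 1, polarity = -1,
                           filter = TRUE, min_separation_ms = 50,
                           tophat_ms = NULL, pre_ms = 40,
                           refine_activation = TRUE) {
  prep <- electro_prep(stack, mask, polarity, filter,
                       min_separation_ms, tophat_ms, pre_ms)
  nb <- length(prep$win_start)
  if (beat_index < 1 || beat_index > nb)
    analysis_error(sprintf("beat_index %d out of range (1..%d)",
                           beat_index, nb))
  res <- beat_durations_cols(prep$traces,
                             as.integer(prep$win_start[beat_index] - 1L),
                             as.integer(prep$win_end[beat_index]),
                             0.8, 10L, prep$dt, 3L,
                             isTRUE(refine_activation))
  act <- res$activation[1, ]             # 0-based sample index
  if (mean(!is.na(act)) < 0.5)
    analysis_error("activation undefined in over half of the mask")
  act_ms <- act * prep$dt
  act_ms <- act_ms - min(act_ms, na.rm = TRUE)
  out <- matrix(NA_real_, prep$dim[1], prep$dim[2])
  out[prep$mask_idx] <- act_ms
  cand <- which(out == 0, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  structure(list(values = out, earliest_site = unname(cand[1, ]),
                 beat_index = beat_index, mask = mask),
            class = "activation_map")
}

#' @export
print.duration_map <- function(x, ...) {
  cat(sprintf("%s map: mean %.1f ms over %d px (%d beats averaged, HR %.0f bpm)\n",
              toupper(sub("d", "D", x$kind)),
              mean(x$values, na.rm = TRUE), sum(!is.na(x$values)),
              x$n_beats_averaged, x$heart_rate))
  invisible(x)
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation map (beat %d): earliest site (%d, %d), span %.1f ms\n",
              x$beat_index, x$earliest_site[1], x$earliest_site[2],
              max(x$values, na.rm = TRUE)))
  invisible(x)
}
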