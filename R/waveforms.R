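#' Analytic action-potential and calcium-transient templates
#'
#' Normalized waveform templates whose duration metrics are exact by
#' construction. Both rise linearly from 0 to 1 over the upstroke, then
#' decay exponentially; the time constant is calibrated so the
#' repolarization threshold is crossed exactly at the requested duration
#' after the activation time (onset of the linear rise, which is where the
#' maximum upstroke derivative lies, earliest tie). For `ap_waveform` the
#' 0.2 level (80% repolarization) is crossed `apd80` ms after activation;
#' for `ca_waveform` the 0.5 level (50% decay) is crossed `catd50` ms after
#' activation. Below 0.1 the exponential shoulder is taken linearly to zero
#' over 10 ms so that successive beats do not overlap at physiological
#' rates; both duration thresholds lie above 0.1 and are unaffected.
#'
#' @param t_rel Time(s) in ms relative to waveform onset; vectorized.
#' @param apd80,catd50 Target duration in ms.
#' @param upstroke_ms,rise_ms Upstroke (rise) duration in ms; must be
#'   positive and smaller than the target duration.
#' @return Normalized deflection values in `[0, 1]`.
#' @examples
#' ap_waveform(c(-1, 1, 52), apd80 = 50, upstroke_ms = 2)
#' @export
ap_waveform <- function(t_rel, apd80, upstroke_ms = 2) {
  template_wave(t_rel, dur = apd80, rise = upstroke_ms, level = 0.2)
}

#' @rdname ap_waveform
#' @export
ca_waveform <- function(t_rel, catd50, rise_ms = 5) {
  template_wave(t_rel, dur = catd50, rise = rise_ms, level = 0.5)
}

# Shared piecewise template: linear rise, exponential shoulder calibrated so
# the value crosses `level` exactly `dur` ms after onset, linear tail 0.1 -> 0.
# `dur` may be a vector recycled against t_rel (per-pixel durations).
template_wave <- function(t_rel, dur, rise, level, tail_ms = 10) {
  if (any(!is.finite(dur)) || !is.finite(rise) || any(dur <= 0) || rise <= 0)
    config_error("waveform duration and rise time must be positive")
  if (any(rise >= dur))
    config_error("rise time must be shorter than the target duration")
  n <- length(t_rel)
  dur <- rep_len(dur, n)
  tau <- (dur - rise) / log(1 / level)
  t_cut <- rise + tau * log(10)           # exponential reaches 0.1 here
  v <- numeric(n)
  up <- t_rel >= 0 & t_rel < rise
  v[up] <- t_rel[up] / rise
  dec <- t_rel >= rise & t_rel < t_cut
  v[dec] <- exp(-(t_rel[dec] - rise) / tau[dec])
  tl <- t_rel >= t_cut & t_rel < t_cut + tail_ms
  v[tl] <- 0.1 * (1 - (t_rel[tl] - t_cut[tl]) / tail_ms)
  v
}

# Support of the template in ms (time after onset at which it returns to 0).
template_span <- function(dur, rise, level, tail_ms = 10) {
  tau <- (dur - rise) / log(1 / level)
  rise + tau * log(10) + tail_ms
}

#' Piecewise-linear drug-response curve
#'
#' A response curve maps recording time (s) to a dimensionless modulation:
#' the true normalized FRET ratio (`applies_to = "delta_fret"`), or a
#' multiplicative scale on action-potential duration, calcium-transient
#' duration or heart rate (`"apd_scale"`, `"catd_scale"`, `"rate_scale"`).
#' Values are interpolated linearly between knots; before the first knot
#' the curve sits at the first knot's value, after the last knot it clamps
#' to the last value.
#'
#' @param times Knot times in seconds, strictly increasing, starting at 0.
#' @param values Knot values (dimensionless); `delta_fret` curves must start
#'   at exactly 1 (baseline normalization).
#' @param applies_to One of `"delta_fret"`, `"apd_scale"`, `"catd_scale"`,
#'   `"rate_scale"`.
#' @return A `response_curve` object.
#' @export
response_curve <- function(times, values,
                           applies_to = c("delta_fret", "apd_scale",
                                          "catd_scale", "rate_scale")) {
  applies_to <- match.arg(applies_to)
  if (length(times) != length(values) || length(times) < 1)
    config_error("times and values must be nonempty and of equal length")
  if (any(diff(times) <= 0))
    config_error("knot times must be strictly increasing")
  if (applies_to == "delta_fret" && values[1] != 1)
    config_error("delta_fret curves must start at exactly 1.0")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 applies_to = applies_to),
            class = "response_curve")
}

# Evaluate a response curve at time t (s), clamped to its end values.
eval_curve <- function(curve, t) {
  stopifnot(inherits(curve, "response_curve"))
  if (length(curve$times) == 1) return(rep(curve$values, length(t)))
  approx(curve$times, curve$values, xout = t, rule = 2)$y
}

#' True cAMP response (normalized FRET ratio) at a given time
#'
#' Evaluates a `delta_fret` response curve: the simulator's ground-truth
#' dFRET = R/R0 time course for one region. Returns 1 (baseline) for times
#' at or before the first knot and clamps to the final knot value.
#'
#' @param t Time(s) in seconds.
#' @param curve A `response_curve` with `applies_to = "delta_fret"`.
#' @return Dimensionless dFRET value(s).
#' @examples
#' camp_response(40, response_preset("ne")$delta_fret)
#' @export
camp_response <- function(t, curve) {
  if (!inherits(curve, "response_curve") || curve$applies_to != "delta_fret")
    config_error("camp_response requires a delta_fret response curve")
  eval_curve(curve, t)
}

#' Drug-response presets
#'
#' Bundled response-curve presets for an acute norepinephrine bolus
#' (`"ne"`), acetylcholine (`"ach"`, reversible cAMP reduction and rate
#' slowing) and tyramine (`"tyramine"`, slower nerve-released NE response).
#' The NE preset encodes the hallmark whole-heart response: dFRET peaking
#' (default 1.2) at 40 s and returning to baseline by 120 s; a biphasic APD
#' scale peaking at 40 s before returning to baseline by 60 s; a monotonic
#' CaTD decrease; and heart rate rising from 300 to 500 bpm.
#'
#' @param drug `"ne"`, `"ach"` or `"tyramine"`.
#' @param peak Peak dFRET amplitude for the NE-like presets (default 1.2).
#' @return A named list of `response_curve`s: `delta_fret` (whole-heart
#'   default), `delta_fret_regions` (named per-region variants expressing
#'   base-vs-apex heterogeneity), `apd_scale`, `catd_scale`, `rate_scale`.
#' @export
response_preset <- function(drug = c("ne", "ach", "tyramine"), peak = 1.2) {
  drug <- match.arg(drug)
  rc <- response_curve
  scale_peak <- function(p) 1 + (p - 1) * ((peak - 1) / 0.2)
  if (drug == "ne") {
    list(
      delta_fret = rc(c(0, 40, 120), c(1, peak, 1), "delta_fret"),
      delta_fret_regions = list(
        "RV base" = rc(c(0, 40, 120), c(1, scale_peak(1.20), 1), "delta_fret"),
        "LV apex" = rc(c(0, 40, 120), c(1, scale_peak(1.15), 1), "delta_fret"),
        "SAN"     = rc(c(0, 40, 120), c(1, scale_peak(1.25), 1), "delta_fret"),
        "LA"      = rc(c(0, 40, 120), c(1, scale_peak(1.15), 1), "delta_fret"),
        "RA"      = rc(c(0, 40, 120), c(1, scale_peak(1.15), 1), "delta_fret")),
      apd_scale  = rc(c(0, 40, 60, 120), c(1, 1.15, 1, 1), "apd_scale"),
      catd_scale = rc(c(0, 60, 120), c(1, 0.85, 0.85), "catd_scale"),
      rate_scale = rc(c(0, 40, 120), c(1, 5 / 3, 1), "rate_scale"))
  } else if (drug == "ach") {
    list(
      delta_fret = rc(c(0, 30, 90), c(1, 0.90, 1), "delta_fret"),
      delta_fret_regions = list(),
      apd_scale  = rc(c(0, 30, 90), c(1, 0.95, 1), "apd_scale"),
      catd_scale = rc(c(0, 30, 90), c(1, 1.05, 1), "catd_scale"),
      rate_scale = rc(c(0, 30, 90), c(1, 0.75, 1), "rate_scale"))
  } else {
    list(
      delta_fret = rc(c(0, 60, 120), c(1, peak - 0.05, 1.05), "delta_fret"),
      delta_fret_regions = list(),
      apd_scale  = rc(c(0, 60, 90, 120), c(1, 1.10, 1, 1), "apd_scale"),
      catd_scale = rc(c(0, 90, 120), c(1, 0.90, 0.90), "catd_scale"),
      rate_scale = rc(c(0, 60, 120), c(1, 1.4, 1.2), "rate_scale"))
  }
}
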