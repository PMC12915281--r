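#' Interleaved acquisition schedule
#'
#' Describes how slow CFP/YFP FRET frames are interleaved with high-rate
#' Vm/Ca mapping bursts. The camera exposes one FRET frame pair every
#' `fret_period` seconds; immediately after each FRET exposure (plus
#' `burst_offset`) the fast cameras record a burst of `burst_duration`
#' seconds at `burst_rate` samples per second. The defaults reproduce a
#' 100 ms FRET exposure every 10 s with 1 kHz bursts of 2 s.
#'
#' @param fret_period Seconds between successive FRET frames.
#' @param fret_exposure FRET exposure time in seconds.
#' @param burst_rate Vm/Ca sampling rate in samples per second.
#' @param burst_duration Duration of each Vm/Ca burst in seconds.
#' @param total_duration Total recording duration in seconds.
#' @param burst_offset Delay in seconds between the end of a FRET exposure
#'   and the start of the following burst (the TTL trigger delay).
#' @return An `acquisition_schedule` object.
#' @examples
#' sched <- acquisition_schedule()
#' fret_times(sched)
#' @export
acquisition_schedule <- function(fret_period = 10, fret_exposure = 0.1,
                                 burst_rate = 1000, burst_duration = 2,
                                 total_duration = 120, burst_offset = 0.05) {
  vals <- c(fret_period = fret_period, fret_exposure = fret_exposure,
            burst_rate = burst_rate, burst_duration = burst_duration,
            total_duration = total_duration, burst_offset = burst_offset)
  if (any(!is.finite(vals)) || any(vals <= 0))
    config_error("all schedule fields must be positive and finite")
  if (fret_exposure + burst_offset + burst_duration > fret_period)
    config_error("fret_exposure + burst_offset + burst_duration must fit within fret_period")
  if (total_duration < fret_period)
    config_error("total_duration must be at least one fret_period")
  structure(as.list(vals), class = "acquisition_schedule")
}

#' @rdname acquisition_schedule
#' @param x An `acquisition_schedule`.
#' @return `fret_times()`: start times (s) of each FRET frame;
#'   `burst_times()`: start times (s) of each Vm/Ca burst. Both begin at 0 /
#'   the first trigger and run through `total_duration`.
#' @export
fret_times <- function(x) {
  stopifnot(inherits(x, "acquisition_schedule"))
  seq(0, x$total_duration, by = x$fret_period)
}

#' @rdname acquisition_schedule
#' @export
burst_times <- function(x) {
  fret_times(x) + x$fret_exposure + x$burst_offset
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    "acquisition schedule: FRET %.0f ms exposure every %g s; burst %g kHz x %g s (offset %g ms); total %g s (%d slots)\n",
    x$fret_exposure * 1000, x$fret_period, x$burst_rate / 1000,
    x$burst_duration, x$burst_offset * 1000, x$total_duration,
    length(fret_times(x))))
  invisible(x)
}
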