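# Shared fixture builders. Everything is generated in code at test time.

qm_channels <- c("cfp", "yfp", "vm", "ca")

identity_bleed <- function() {
  b <- diag(4)
  dimnames(b) <- list(qm_channels, qm_channels)
  b
}

# Noise-free, vignette-free, unmixed, unquantized channels: the exact-oracle
# configuration.
clean_channels <- function(...) {
  channel_model(noise_sd = 0, vignette_strength = 0,
                bleedthrough = identity_bleed(), quantize = FALSE, ...)
}

# A flat-response curve set (baseline conditions throughout).
flat_curves <- function() {
  list(delta_fret = response_curve(0, 1, "delta_fret"),
       apd_scale = response_curve(0, 1, "apd_scale"),
       catd_scale = response_curve(0, 1, "catd_scale"),
       rate_scale = response_curve(0, 1, "rate_scale"))
}

# Build a burst stack directly from a per-pixel trace generator, bypassing
# the simulator (used to probe the electro pipeline in isolation).
stack_from_traces <- function(rows, cols, times_ms, trace_fn) {
  arr <- array(0, dim = c(rows, cols, length(times_ms)))
  for (r in seq_len(rows)) for (c in seq_len(cols))
    arr[r, c, ] <- trace_fn(r, c, times_ms)
  frame_stack(arr, times_ms / 1000, 0.1)
}

# O(n^2) two-sample KS statistic by explicit ECDF sweep (test oracle).
ks_brute <- function(a, b) {
  xs <- c(a, b)
  max(vapply(xs, function(x) abs(mean(a <= x) - mean(b <= x)), 1))
}

# Brute-force grayscale opening with flat element of `w` samples (clipped
# at the edges), via direct min/max scans (test oracle).
open_brute <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  er <- vapply(seq_len(n), function(i)
    min(x[max(1, i - h):min(n, i + h)]), 1)
  vapply(seq_len(n), function(i)
    max(er[max(1, i - h):min(n, i + h)]), 1)
}
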