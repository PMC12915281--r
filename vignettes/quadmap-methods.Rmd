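---
title: "Methods: quadruple-parametric FRET and optical mapping analysis"
author: "quadmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadruple-parametric FRET and optical mapping analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadmap)
```

## The measurement problem

Wide-field optical mapping of a Langendorff-perfused heart records
transmembrane potential (Vm, via a voltage-sensitive dye such as RH237) and
intracellular calcium (via Rhod-2 or X-Rhod-1) at kilohertz rates, while a
genetically encoded Epac-based CFP/YFP FRET biosensor reports cAMP on a
time scale of seconds. Because the green excitation used for the dyes
overlaps YFP emission, the instrument interleaves the two modalities: one
100 ms CFP/YFP exposure every 10 s, each immediately followed by a
triggered 2 s Vm/Ca burst sampled at 1 kHz. The FRET camera resolves
7.24 mm over 1024 pixels (~7 um/px); the mapping cameras resolve 10 mm
over 100 pixels (100 um/px).

`quadmap` implements the analysis chain for such recordings — ratiometric
cAMP maps, action-potential and calcium-transient duration maps, pacemaker
localization, spectral-crosstalk checks, and cross-camera colocalization —
together with a synthetic-recording generator whose every output has an
analytic ground truth, so that each stage of the chain is testable without
experimental data.

## cAMP readout: R and dFRET

cAMP binding to the Epac sensor reduces energy transfer, raising donor
(CFP) and lowering acceptor (YFP) emission. The readout is computed
pixel-by-pixel:

* `R = CFP / YFP` after dark-offset subtraction;
* `R0` = mean of `R` over a configurable pre-stimulus baseline window
  (reducing to a single frame when the window has length 1);
* `dFRET = R / R0`.

Normalizing by `R0` cancels static gain differences, uneven illumination
and cardiac curvature, which is why regional comparisons use dFRET rather
than R. The per-pixel mean of dFRET over the baseline window is exactly 1
by construction, and dFRET is invariant both to common gain changes and to
a gain change in a single channel (the change cancels between `R` and
`R0`). Dark pixels whose YFP count never exceeds a floor (recommended:
5 x the camera offset) are removed from the mask rather than allowed to
produce unstable ratios. An unsubtracted camera offset compresses `R`
toward 1 — with the default synthetic gains, by about 1% at a 20% FRET
response — so `compute_ratio()` takes the offset explicitly and the
pipeline passes the configured value through.

ROI time courses average the per-pixel dFRET over the ROI (ratio first,
then spatial averaging). Bolus-response metrics are: `max_ratio`, the
maximum dFRET after the baseline window (earliest frame on ties);
`time_to_peak`; and `decay_t50`, the time from the peak to the first
post-peak crossing of the level halfway between the peak and baseline 1,
linearly interpolated between frames. Halfway-to-baseline (rather than
halfway to any post-drug plateau) was chosen because it is well defined
for every transient response; traces that never rise more than
`min_response` (default 0.01) above baseline report undefined metrics
rather than an error.

## Electrophysiology: filtering, beats, durations

Burst stacks pass through, in order:

1. **Spatial Gaussian filter**, 3 x 3 support with sigma = 1 px; the kernel
   is the normalized outer product of `c(exp(-0.5), 1, exp(-0.5))`.
   Support alone does not fix a Gaussian, so sigma = 1 px is declared
   explicitly and `gaussian_kernel3()` prints the exact kernel. Borders
   replicate the edge row/column.
2. **Polarity normalization**: RH237-like dyes deflect downward on
   depolarization, so the Vm channel defaults to polarity -1 and calcium
   to +1; traces are flipped so upstrokes are positive before any
   detection.
3. **Top-hat baseline correction**: subtraction of the grayscale
   morphological opening (erosion then dilation, flat structuring element)
   of the trace. The opening tracks the diastolic lower envelope including
   slow drift while ignoring deflections narrower than the element. The
   element defaults to 1.5 x the median beat interval, estimated from a
   derivative-based beat detection that is itself insensitive to slow
   drift. A steep drift (comparable to the deflection amplitude per beat)
   biases the opening near peaks; at physiological drift rates the effect
   is negligible.
4. **Beat detection** on the mask-mean reference trace: peaks of the
   forward-difference derivative above 0.5 x its maximum, separated by at
   least `min_separation_ms` (default 50 ms, adequate up to 1200 bpm).
   Heart rate is 60000 / mean inter-activation interval.

Per beat and per pixel:

* **Activation time** is the earliest maximum of the forward difference
  within the beat window. Differences within a relative 1e-9 of the
  maximum count as ties (earliest wins): an idealized linear upstroke has
  an exactly flat derivative, and without the tolerance floating-point
  jitter selects an arbitrary rise sample.
* **Duration** (APD80 with level 0.8, CaTD50 with level 0.5) runs from
  activation to the first post-peak crossing of
  `peak - level * (peak - diastolic baseline)`, linearly interpolated
  between samples. The diastolic baseline is the mean of the 10 ms
  preceding the upstroke (per beat, not per trace, so successive beats at
  high rate remain comparable).

Two numerical choices matter at 1 kHz sampling and are exposed as
parameters:

* **Sub-sample activation for durations** (`refine_activation`, default
  on): the partial forward difference immediately before the first
  maximal one equals the sub-sample onset fraction of a linear upstroke,
  so the duration kernel subtracts it from the activation sample. With
  sample-resolution activation the quantization alone produces up to
  ~1.4 ms of one-sided duration error; with refinement, zero-noise
  recovery over APD80 in {30, 50, 70} ms and CaTD50 in {25, 40, 55} ms is
  within one sample everywhere. `activation_time()` itself reports sample
  resolution by default with optional parabolic refinement.
* **Crossing hold** (`hold_ms`, default 3 ms): the crossing is accepted
  only if the trace stays at or below threshold for this long. A plain
  first-crossing rule is biased several milliseconds early under noise
  (the earliest downward noise excursion wins); the hold suppresses
  single-sample excursions while leaving noise-free traces untouched.

Duration maps average the first `n_beats` (default 10) complete
consecutive beats per pixel; bursts with fewer usable beats average what
is available and record the count. Activation maps report per-pixel
activation relative to the earliest pixel; the earliest site (row-major
first among exact ties) localizes the leading pacemaker in atrial views.

The 3 x 3 spatial filter deliberately trades a small wavefront blur for
noise suppression: at mask edges it can shift measured durations by up to
about 1 ms at zero noise, because neighboring pixels activate at slightly
different times. The package's recovery tests therefore assert the
one-sample bound on unfiltered maps and a 1.5 ms bound on filtered ones;
at the 5% noise level the filter is what keeps 95% of pixels within 3 ms.

## Crosstalk validation

`ks_compare()` wraps the two-sample Kolmogorov-Smirnov test (asymptotic
p-values; exact small-n p-values are out of scope) for comparing dFRET
traces across dye-loading conditions. The default mode compares value
distributions, matching the test's definition; a `paired_difference` mode
(two-sample KS of the time-paired differences against their negation,
i.e. a symmetry-about-zero test) is provided as a labeled alternative
because the choice is not canonical. `bleedthrough_fraction()` quantifies
channel contamination as the least-squares slope of the target on the
source trace, clipped to [0, 1]; both traces should be baseline-corrected
and, when estimated from noisy single pixels, the slope is attenuated by
source-channel noise, so ROI-mean traces are recommended.

## Cross-camera colocalization and statistics

The FRET and mapping cameras share optics and differ essentially in
magnification and offset, so fiducial registration fits a 4-parameter
similarity transform (scale, rotation, translation; reflection excluded;
minimum two point pairs) by closed-form complex least squares. ROIs map
between grids by transforming pixel centers and rasterizing the convex
hull on the target grid (pixel-center inclusion; each transformed point's
nearest pixel is also kept so one-pixel ROIs survive). Regional statistics
follow the field's conventions: mean +/- SEM (sample SD / sqrt(N), N =
hearts) and paired two-tailed t-tests, with no multiple-testing
correction applied (matching how such regional comparisons are reported);
zero-variance nonzero differences report the limit p = 0 with a warning.

## The synthetic-data generator

`render_recording()` emulates the instrument and the physiology the
analysis chain is meant to recover. Its defaults are the package's study
conditions and were chosen once:

| quantity | default | note |
|---|---|---|
| schedule | 100 ms FRET exposure / 10 s, 1 kHz x 2 s bursts | instrument timing |
| dFRET response (NE) | knots (0, 1), (40 s, 1.2), (120 s, 1) | peak time from the biphasic response; amplitude 1.2 is a synthetic default |
| APD scale (NE) | (0, 1), (40 s, 1.15), (60 s, 1), (120 s, 1) | biphasic: maximal at ~40 s, near baseline by ~60 s |
| CaTD scale (NE) | (0, 1), (60 s, 0.85), (120 s, 0.85) | monotonic decrease |
| heart rate | 300 bpm rising to 500 bpm at 40 s | NE chronotropy; magnitudes synthetic |
| base APD80 / CaTD50 | ventricle: 55 -> 45 ms base-to-apex gradient / 40 ms; atria: 35 / 30 ms | mouse-scale values |
| conduction velocity | 0.5 mm/ms ventricle, 0.3 mm/ms atria | focal wavefront |
| modulation depth | 0.3 of resting fluorescence | typical optical-mapping fractional signal |
| noise SD | 5% of the deflection amplitude (mapping channels) | stochastic test condition |
| bleed-through | 0.05 Ca -> Vm (linear, before noise) | "slight" contamination; 0.08 in recovery examples |
| vignetting | radial cosine falloff, strength 0.3 | curvature-induced edge dimming |

Waveforms are analytic templates: a linear rise (2 ms Vm, 5 ms Ca)
followed by an exponential shoulder whose time constant is calibrated so
the duration definitions hold exactly — the 0.2 level is crossed exactly
APD80 after onset, the 0.5 level exactly CaTD50 after onset. Below 0.1
the shoulder is taken linearly to zero over 10 ms so consecutive beats do
not overlap at the simulated rates. Beat onsets at the focal source are
rounded to the sampling grid, which makes the focal pixel the strict
earliest-activation site; other pixels activate after geodesic distance /
conduction velocity (the elliptical masks are convex, so Euclidean
distance suffices).

FRET transduction uses `CFP = gain * dFRET^a`, `YFP = gain * dFRET^-b`
(defaults a = b = 1/2): CFP rises and YFP falls as cAMP rises, the
CFP/YFP ratio equals `dFRET^(a+b)` — exactly the true dFRET when
a + b = 1 — and a linearized small-signal expansion reproduces the
familiar anti-correlated form `gain * (1 +/- 0.5 (dFRET - 1))`. A strictly
linear transduction cannot make the recovered ratio equal the true dFRET
for any fixed coefficients, which would leave the pipeline without an
exact oracle; exactness was preferred.

Counts are vignetted, linearly mixed across channels, offset, Gaussian
noise is added, and frames are quantized to 16-bit integers
(`quantize = FALSE` disables quantization for continuous-valued oracle
comparisons, since 16-bit rounding alone contributes ~2.5e-4 relative
error). Identical configuration and seed give bit-identical output.

What the generator does **not** emulate: motion and contraction (optical
mapping experiments suppress these pharmacologically), photon-shot
(signal-dependent) noise, photobleaching, 3-D geometry and depth
contributions, tissue-specific ion-channel kinetics beyond the template
shapes, and pharmacokinetics of the applied drugs. Passing tests
therefore demonstrate the correctness of the analysis chain on data whose
generative assumptions are known, not robustness to every artifact of
real recordings.

## Problem sizes and determinism

The test-suite simulations use 32-48 px grids and 10-60 s schedules; the
end-to-end acceptance run uses the full instrument schedule (120 s, 13
interleaved slots) on a 64 x 64 grid, chosen to keep a complete run in
the low minutes on one CPU while leaving thousands of mask pixels per
map. All randomness flows from a single integer seed through the
generator; reruns of `run_pipeline()` with the same config are
byte-identical, and every output CSV embeds an MD5 hash of the
configuration.

## Known limitations

* The KS p-values are asymptotic and conservative below n ~ 25 per group.
* `decay_t50` is undefined until the trace actually falls halfway back to
  baseline within the recording, so short recordings report `NA`.
* Activation refinement assumes an approximately linear upstroke over one
  sample; strongly sigmoidal upstrokes at low sampling rates revert to
  sample-resolution accuracy.
* The similarity registration excludes shear; genuinely affine
  distortions between cameras would need the affine extension.
* On-disk float maps are stored as normalized 32-bit TIFF with
  scale/offset in the JSON sidecar; round-trips are exact to float
  precision, not bit-exact (16-bit count stacks are bit-exact).

## A minimal session

```{r example, eval = FALSE}
g <- build_geometry(64, 64, "ventricle_anterior")
rec <- render_recording(g, acquisition_schedule(total_duration = 120),
                        response_preset("ne"), seed = 1)

movie <- compute_ratio(rec$fret, baseline_window = 1,
                       dark_offset = rec$channels$offset[c("cfp", "yfp")])
base <- roi_trace(movie, g$regions[["RV base"]], "RV base")

apd <- duration_map(rec$bursts[[5]]$vm, g$mask, "apd80")
cat(base$max_ratio, apd$heart_rate, mean(apd$values, na.rm = TRUE))
```
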