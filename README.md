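# quadmap

Analysis of quadruple-parametric whole-heart fluorescence imaging: slow
ratiometric CFP/YFP FRET acquisition (an Epac-based cAMP biosensor
readout) interleaved with high-rate optical-mapping bursts of
transmembrane potential (Vm) and intracellular Ca²⁺ in Langendorff-perfused
hearts. The package is written for cardiac electrophysiology and signaling
labs that need to turn such recordings into cAMP maps, action-potential /
calcium-transient duration maps and pacemaker localizations — and for
anyone who wants to validate that chain against data with a known ground
truth.

## What it computes

**cAMP (FRET) arm.** Pixel-wise ratio R = CFP/YFP (after dark-offset
subtraction), baseline ratio R₀ over a pre-stimulus window, and
ΔFRET = R/R₀ maps; ROI time courses (ratio first, then spatial averaging);
bolus-response metrics Max R/R₀, time-to-peak and 50%-decay time;
cross-sectional intensity profiles; automated registration of the
split-detector CFP/YFP half-images by exhaustive cross-correlation.

**Electrophysiology arm.** Per burst: 3×3 spatial Gaussian filtering
(σ = 1 px), polarity normalization, top-hat (morphological opening)
baseline-drift correction, derivative-based beat detection and heart rate;
per pixel and beat: activation time at the maximum upstroke derivative,
APD₈₀ and CaTD₅₀ from activation to the 80%-repolarization /
50%-decay crossing (linearly interpolated), averaged over 10 consecutive
beats; activation maps whose earliest site localizes the leading pacemaker
(sinoatrial node) in atrial views.

**Validation arm.** Two-sample Kolmogorov–Smirnov comparison of ΔFRET
traces across dye-loading conditions; channel bleed-through as the
least-squares slope of one channel on another; fiducial-based similarity
registration between the 7 µm/px FRET grid and the 100 µm/px mapping grid
with ROI colocalization; paired two-tailed t-tests and mean ± SEM regional
summaries.

**Synthetic data.** `render_recording()` generates the full interleaved
acquisition — 100 ms FRET exposure every 10 s, 1 kHz × 2 s Vm/Ca bursts —
over an elliptical heart geometry with labeled regions, focal activation
wavefronts, piecewise-linear drug-response curves (norepinephrine,
acetylcholine, tyramine presets), analytic AP/Ca waveform templates whose
durations are exact by construction, vignetting, channel bleed-through,
Gaussian noise and 16-bit quantization, returning per-pixel ground truth
for every quantity the pipeline estimates.

## Worked example

Simulate the default norepinephrine bolus on a 64×64 ventricular
preparation and analyze it:

```r
library(quadmap)

g <- build_geometry(64, 64, "ventricle_anterior")
rec <- render_recording(g, acquisition_schedule(total_duration = 120),
                        response_preset("ne"), seed = 1)

movie <- compute_ratio(rec$fret, baseline_window = 1,
                       dark_offset = rec$channels$offset[c("cfp", "yfp")])
base <- roi_trace(movie, g$regions[["RV base"]], "RV base")
sprintf("RV base: Max R/R0 = %.3f at %g s; decay t50 = %.1f s",
        base$max_ratio, base$time_to_peak, base$decay_t50)
#> "RV base: Max R/R0 = 1.200 at 40 s; decay t50 = 39.8 s"

duration_map(rec$bursts[[1]]$vm, g$mask, "apd80")   # baseline burst (t = 0)
#> APD80 map: mean 49.3 ms over 2264 px (10 beats averaged, HR 301 bpm)
duration_map(rec$bursts[[5]]$vm, g$mask, "apd80")   # burst at t = 40 s
#> APD80 map: mean 57.4 ms over 2264 px (10 beats averaged, HR 500 bpm)
```

The ROI trace peaks at ΔFRET = 1.20 forty seconds after the bolus and
decays halfway back to baseline 39.8 s later; whole-mask APD₈₀ lengthens
from ~49 ms at baseline to ~57 ms at the 40 s burst while heart rate rises
from 300 to 500 bpm — the biphasic APD prolongation and chronotropic
response the simulator's presets encode. `run_pipeline()` chains all of
this (simulated or file-based input, config-driven) into per-slot summary
tables, and `inst/cli/quadmap` exposes `simulate`, `fret`, `map`,
`validate`, `coloc` and `run` subcommands for shell use.

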