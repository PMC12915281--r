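test_that("the spatial Gaussian kernel is normalized and acts as expected", {
  k <- gaussian_kernel3()
  expect_equal(sum(k), 1)
  k1 <- c(exp(-0.5), 1, exp(-0.5))
  expect_equal(k, outer(k1, k1) / sum(outer(k1, k1)))
  # constant frame unchanged
  const <- matrix(4.2, 10, 12)
  expect_equal(spatial_filter(const), const)
  # interior impulse: response equals the kernel, mass conserved
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- spatial_filter(imp)
  expect_equal(out[4:6, 4:6], k)
  expect_equal(sum(out), 1, tolerance = 1e-9)
})

test_that("top-hat correction removes drift while preserving pulse amplitude", {
  tms <- 0:2999
  pulses <- Reduce(`+`, lapply(seq(50, 2850, 200), function(o)
    ap_waveform(tms - o, 50, 2)))
  drift <- 0.002 * tms                     # linear drift
  tr <- optical_trace(tms, pulses + drift + 3)
  corr <- baseline_correct(tr, window_ms = 300)
  # matches the brute-force morphological oracle exactly
  expect_equal(corr$values,
               tr$values - open_brute(tr$values, 301), tolerance = 1e-12)
  # diastolic samples (just before each upstroke) near zero
  dia <- corr$values[seq(45, 2845, 200)]
  expect_true(all(abs(dia) < 0.02))
  # drift-free trace: baseline offset removed, pulse amplitude within 1%
  # of truth with window = 1.5 x beat period
  tr2 <- optical_trace(tms, pulses + 3)
  corr2 <- baseline_correct(tr2, window_ms = 300)
  expect_equal(corr2$values, pulses, tolerance = 0.01)
  peaks <- vapply(seq(50, 2850, 200), function(o)
    max(corr2$values[(o - 5):(o + 80)]), 1)
  expect_true(all(abs(peaks - 1) < 0.01))
  expect_error(baseline_correct(tr, window_ms = 0.5),
               class = "quadmap_config_error")
})

test_that("beat detection counts rate correctly and tolerates flat traces", {
  tms <- 0:1999
  pulses <- Reduce(`+`, lapply(seq(20, 1920, 100), function(o)
    ap_waveform(tms - o, 40, 2)))
  bs <- detect_beats(optical_trace(tms, pulses))
  expect_equal(bs$n_beats, 20)
  expect_equal(bs$heart_rate, 600)
  flat <- detect_beats(optical_trace(tms, rep(1, 2000)))
  expect_equal(flat$n_beats, 0)
  # simulated burst at a configured 450 bpm
  g <- build_geometry(32, 32, "ventricle_anterior")
  cur <- flat_curves()
  cur$rate_scale <- response_curve(0, 1.5, "rate_scale")   # 450 bpm
  rec <- render_recording(g, acquisition_schedule(total_duration = 10),
                          cur, seed = 4, base_apd80 = 50, base_catd50 = 40)
  st <- rec$bursts[[1]]$vm
  idx <- which(g$mask)
  ref <- optical_trace((st$times - st$times[1]) * 1000,
                       -colMeans(matrix(st$data, ncol = 2000)[idx, ]))
  ref <- baseline_correct(ref, 1.5 * 60000 / 450)
  expect_equal(detect_beats(ref)$heart_rate, 450, tolerance = 5)
})

test_that("activation time follows the maximum upstroke derivative with earliest ties", {
  tms <- 0:299
  # linear upstroke starting at sample 101 (t = 100): constant derivative,
  # earliest tie wins
  ramp <- pmin(pmax((tms - 100) / 10, 0), 1)
  expect_equal(activation_time(optical_trace(tms, ramp), 50:200), 100)
  # sigmoid upstroke: the forward difference is maximal for the interval
  # centered on the inflection point t0 = 150.5
  sig <- 1 / (1 + exp(-(tms - 150.5) / 4))
  expect_equal(activation_time(optical_trace(tms, sig), 50:300), 150)
  expect_true(is.na(activation_time(optical_trace(tms, rev(ramp)), 150:250)))
})

test_that("durations match the closed-form trapezoid", {
  tms <- 0:199
  trap <- approx(c(0, 10, 12, 40, 100, 200), c(0, 0, 1, 1, 0, 0),
                 xout = tms)$y
  tr <- optical_trace(tms, trap)
  # activation at 10 ms; 0.2 crossing on the fall at 88 ms
  expect_equal(apd(tr, 1:150, level = 0.8), 78)
  expect_equal(apd(tr, 1:150, level = 0.5), 60)
})

test_that("duration and activation analysis are shift- and scale-invariant", {
  tms <- 0:999
  v <- ap_waveform(tms - 100, 50, 2)
  tr <- optical_trace(tms, v)
  a0 <- activation_time(tr, 1:400)
  d0 <- apd(tr, 1:400)
  for (k in c(17, 180)) {
    shifted <- optical_trace(tms, c(rep(0, k), v[1:(1000 - k)]))
    expect_equal(activation_time(shifted, 1:600), a0 + k)
    expect_equal(apd(shifted, 1:600), d0, tolerance = 1e-9)
  }
  for (cc in c(0.2, 5, 1234)) {
    scaled <- optical_trace(tms, v * cc)
    expect_equal(activation_time(scaled, 1:400), a0)
    expect_equal(apd(scaled, 1:400), d0, tolerance = 1e-9)
  }
})

test_that("duration maps recover homogeneous and regional ground truth", {
  g <- build_geometry(32, 32, "ventricle_anterior")
  s <- acquisition_schedule(total_duration = 10)
  rec <- render_recording(g, s, flat_curves(), clean_channels(), seed = 1,
                          base_apd80 = 50, base_catd50 = 40)
  dm <- duration_map(rec$bursts[[1]]$vm, g$mask, "apd80", filter = FALSE)
  expect_equal(dm$n_beats_averaged, 10)
  expect_true(all(abs(dm$values[g$mask] - 50) <= 1))
  expect_true(all(is.na(dm$values[!g$mask])))
  cm <- duration_map(rec$bursts[[1]]$ca, g$mask, "catd50", filter = FALSE)
  expect_true(all(abs(cm$values[g$mask] - 40) <= 1))
  # the 3 x 3 spatial filter blurs across the wavefront: still close
  dmf <- duration_map(rec$bursts[[1]]$vm, g$mask, "apd80")
  expect_true(all(abs(dmf$values[g$mask] - 50) <= 1.5))
  # base/apex APD gradient 55/45 ms recovered in the ROI means
  base_map <- matrix(50, 32, 32)
  base_map[g$regions[["RV base"]]] <- 55
  base_map[g$regions[["LV apex"]]] <- 45
  rec2 <- render_recording(g, s, flat_curves(), clean_channels(), seed = 1,
                           base_apd80 = base_map, base_catd50 = 40)
  dm2 <- duration_map(rec2$bursts[[1]]$vm, g$mask, "apd80")
  expect_equal(mean(dm2$values[g$regions[["RV base"]]]), 55, tolerance = 1)
  expect_equal(mean(dm2$values[g$regions[["LV apex"]]]), 45, tolerance = 1)
})

test_that("beat averaging uses the first 10 of the available complete beats", {
  g <- build_geometry(32, 32, "ventricle_anterior")
  cur <- flat_curves()
  cur$rate_scale <- response_curve(0, 1.2, "rate_scale")  # 360 bpm: 12 beats
  rec <- render_recording(g, acquisition_schedule(total_duration = 10),
                          cur, clean_channels(), seed = 1,
                          base_apd80 = 50, base_catd50 = 40)
  expect_length(rec$truth$beat_onsets[[1]], 12)
  dm <- duration_map(rec$bursts[[1]]$vm, g$mask, "apd80", n_beats = 10)
  expect_equal(dm$n_beats_averaged, 10)
})

test_that("duration recovery stays within one sample over the parameter grid", {
  g <- build_geometry(32, 32, "ventricle_anterior")
  s <- acquisition_schedule(total_duration = 10)
  for (apd_true in c(30, 50, 70)) for (catd_true in c(25, 40, 55)) {
    rec <- render_recording(g, s, flat_curves(), clean_channels(), seed = 1,
                            base_apd80 = apd_true, base_catd50 = catd_true)
    dm <- duration_map(rec$bursts[[1]]$vm, g$mask, "apd80", filter = FALSE)
    cm <- duration_map(rec$bursts[[1]]$ca, g$mask, "catd50", filter = FALSE)
    expect_true(all(abs(dm$values[g$mask] - apd_true) <= 1),
                label = sprintf("APD80 %d/%d", apd_true, catd_true))
    expect_true(all(abs(cm$values[g$mask] - catd_true) <= 1),
                label = sprintf("CaTD50 %d/%d", apd_true, catd_true))
  }
})

test_that("APD80 errors stay small under 5% amplitude noise", {
  g <- build_geometry(32, 32, "ventricle_anterior")
  ch <- channel_model(bleedthrough = identity_bleed())  # noise SD 30 = 5% of 600
  rec <- render_recording(g, acquisition_schedule(total_duration = 10),
                          flat_curves(), ch, seed = 42,
                          base_apd80 = 50, base_catd50 = 40)
  dm <- duration_map(rec$bursts[[1]]$vm, g$mask, "apd80")
  err <- abs(dm$values[g$mask] - 50)
  expect_gte(mean(err <= 3, na.rm = TRUE), 0.95)
})

test_that("activation maps localize the focal source and order the wavefront", {
  # focal atrial simulation: earliest site at the seeded SAN source
  g <- build_geometry(40, 40, "atria_posterior")
  rec <- render_recording(g, acquisition_schedule(total_duration = 10),
                          flat_curves(), clean_channels(), seed = 1,
                          base_apd80 = 35, base_catd50 = 30)
  # unfiltered at zero noise: the focal pixel is the strict argmin
  am <- activation_map(rec$bursts[[1]]$vm, g$mask, beat_index = 1,
                       filter = FALSE)
  expect_equal(am$earliest_site, g$focal_source)
  expect_equal(min(am$values, na.rm = TRUE), 0)
  # activation differences track distance / conduction velocity within 1 sample
  truth <- rec$truth$activation_time
  resid <- am$values - truth
  expect_lt(diff(range(resid[g$mask])), 1 + 1e-9)
  # the 3 x 3 filter may merge sub-sample ties but stays near the source
  amf <- activation_map(rec$bursts[[1]]$vm, g$mask, beat_index = 1)
  expect_lt(sqrt(sum((amf$earliest_site - g$focal_source)^2)), 5)
  expect_error(activation_map(rec$bursts[[1]]$vm, g$mask, beat_index = 99),
               class = "quadmap_analysis_error")
})

test_that("simultaneous activation yields a zero map with row-major tie-break", {
  tms <- 0:999
  v <- ap_waveform(tms - 100, 50, 2)
  st <- stack_from_traces(12, 12, tms, function(r, c, t) v)
  mask <- matrix(TRUE, 12, 12)
  am <- activation_map(st, mask, beat_index = 1, polarity = 1,
                       filter = FALSE)
  expect_true(all(am$values == 0))
  expect_equal(am$earliest_site, c(1, 1))
})

test_that("a planar wave produces linear isochrones", {
  tms <- 0:999
  st <- stack_from_traces(16, 16, tms, function(r, c, t)
    ap_waveform(t - 100 - 3 * (r - 1), 50, 2))
  mask <- matrix(TRUE, 16, 16)
  am <- activation_map(st, mask, beat_index = 1, polarity = 1,
                       filter = FALSE)
  for (r in 1:16)
    expect_equal(unique(am$values[r, ]), 3 * (r - 1))
})
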