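make_rec <- function(cfp_arr, yfp_arr, times = seq_len(dim(cfp_arr)[3]) - 1,
                     mask = matrix(TRUE, dim(cfp_arr)[1], dim(cfp_arr)[2])) {
  fret_recording(frame_stack(cfp_arr, times), frame_stack(yfp_arr, times),
                 mask)
}

test_that("constant channels give R = CFP/YFP and dFRET = 1", {
  cfp <- array(200, dim = c(8, 8, 5))
  yfp <- array(100, dim = c(8, 8, 5))
  rm <- compute_ratio(make_rec(cfp, yfp), 1:2)
  expect_true(all(rm$r == 2))
  expect_true(all(rm$delta == 1))
  expect_true(all(rm$r0 == 2))
})

test_that("per-pixel mean dFRET over the baseline window is 1 by construction", {
  set.seed(11)
  cfp <- array(rnorm(8 * 8 * 6, 200, 20), dim = c(8, 8, 6))
  yfp <- array(rnorm(8 * 8 * 6, 100, 10), dim = c(8, 8, 6))
  rm <- compute_ratio(make_rec(cfp, yfp), 1:3)
  base_mean <- apply(rm$delta[, , 1:3], c(1, 2), mean)
  expect_equal(base_mean, matrix(1, 8, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dFRET is invariant to common and single-channel gain changes", {
  set.seed(12)
  cfp <- array(rnorm(6 * 6 * 5, 200, 10), dim = c(6, 6, 5))
  yfp <- array(rnorm(6 * 6 * 5, 100, 5), dim = c(6, 6, 5))
  rm <- compute_ratio(make_rec(cfp, yfp), 1:2)
  for (cc in c(0.5, 3, 17)) {
    both <- compute_ratio(make_rec(cfp * cc, yfp * cc), 1:2)
    expect_equal(both$delta, rm$delta, tolerance = 1e-12)
    # CFP-only gain scales R by c but cancels in dFRET (R0 scales too)
    one <- compute_ratio(make_rec(cfp * cc, yfp), 1:2)
    expect_equal(one$r, rm$r * cc, tolerance = 1e-9)
    expect_equal(one$delta, rm$delta, tolerance = 1e-9)
  }
})

test_that("ROI dFRET equals the simulator truth at zero noise with a = b", {
  g <- build_geometry(48, 48, "ventricle_anterior")
  s <- acquisition_schedule(total_duration = 60)
  rec <- render_recording(g, s, response_preset("ne"), clean_channels(),
                          seed = 1)
  rm <- compute_ratio(rec$fret, 1,
                      dark_offset = rec$channels$offset[c("cfp", "yfp")])
  truth <- rec$truth$delta_fret_true
  for (nm in c("RV base", "LV apex")) {
    tr <- roi_trace(rm, g$regions[[nm]], nm)
    expect_lt(max(abs(tr$values - truth[[nm]])), 1e-6)
  }
  expect_equal(roi_trace(rm, g$regions[["RV base"]], "b")$max_ratio, 1.2,
               tolerance = 1e-6)
})

test_that("ROI traces reduce correctly for uniform movies and singletons", {
  cfp <- array(200, dim = c(8, 8, 5))
  yfp <- array(100, dim = c(8, 8, 5))
  rm <- compute_ratio(make_rec(cfp, yfp), 1:2)
  expect_true(all(roi_trace(rm, matrix(TRUE, 8, 8), "all")$values == 1))
  set.seed(3)
  cfp2 <- array(rnorm(8 * 8 * 5, 200, 30), dim = c(8, 8, 5))
  rm2 <- compute_ratio(make_rec(cfp2, yfp), 1:2)
  one <- matrix(FALSE, 8, 8); one[3, 5] <- TRUE
  expect_equal(roi_trace(rm2, one, "px")$values, rm2$delta[3, 5, ])
  outside <- matrix(FALSE, 8, 8)
  expect_error(roi_trace(rm2, outside, "none"),
               class = "quadmap_analysis_error")
})

test_that("dark pixels are removed by the YFP floor", {
  cfp <- array(200, dim = c(8, 8, 5))
  yfp <- array(100, dim = c(8, 8, 5))
  yfp[1, 1, 3] <- 2                      # transiently dark pixel
  rm <- compute_ratio(make_rec(cfp, yfp), 1:2, yfp_floor = 10)
  expect_false(rm$mask[1, 1])
  expect_true(is.na(rm$delta[1, 1, 1]))
  expect_error(compute_ratio(make_rec(cfp, yfp), 1:2, yfp_floor = 1e6),
               class = "quadmap_analysis_error")
})

test_that("response metrics match the closed-form triangle trace", {
  times <- seq(0, 120, 10)
  vals <- approx(c(0, 40, 120), c(1, 1.4, 1), xout = times)$y
  tr <- list(times = times, values = vals)
  m <- response_metrics(tr, baseline_window = 1)
  expect_equal(unname(m["max_ratio"]), 1.4)
  expect_equal(unname(m["time_to_peak"]), 40)
  # halfway level 1.2 reached at t = 80 on the linear descent
  expect_equal(unname(m["decay_t50"]), 40)
  flat <- list(times = times, values = rep(1, length(times)))
  expect_true(all(is.na(response_metrics(flat, baseline_window = 1))))
})

test_that("NE-preset decay time matches the analytic half-return of the knots", {
  g <- build_geometry(32, 32, "ventricle_anterior")
  s <- acquisition_schedule(total_duration = 120)
  rec <- render_recording(g, s, response_preset("ne"), clean_channels(),
                          seed = 1)
  rm <- compute_ratio(rec$fret, 1,
                      dark_offset = rec$channels$offset[c("cfp", "yfp")])
  tr <- roi_trace(rm, g$regions[["RV base"]], "RV base")
  # knots (0,1),(40,1.2),(120,1): halfway 1.1 on the descent at t = 80
  expect_equal(unname(tr$decay_t50), 40, tolerance = 1e-6)
})

test_that("split-image registration recovers constructed shifts", {
  set.seed(21)
  base <- matrix(0, 40, 40)
  base[10:30, 8:25] <- outer(1:21, 1:18) / 100 + 5
  arr <- array(rep(base, 3), dim = c(40, 40, 3))
  cfp <- frame_stack(arr, 0:2)
  shift_img <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    ri <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
    ci <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
    out[ri, ci] <- m[ri - dy, ci - dx]
    out
  }
  expect_equal(register_split(cfp, cfp, 5)$shift, c(dy = 0, dx = 0))
  moved <- array(rep(shift_img(base, 3, -2), 3), dim = c(40, 40, 3))
  res <- register_split(cfp, frame_stack(moved, 0:2), 5)
  expect_equal(res$shift, c(dy = 3, dx = -2))
  # registered YFP matches CFP where defined
  ok <- !is.na(res$yfp$data[, , 1])
  expect_equal(res$yfp$data[, , 1][ok], arr[, , 1][ok])
  # robust to noise at SNR ~ 10
  noisy <- moved + array(rnorm(length(moved), 0, max(base) / 10),
                         dim = dim(moved))
  expect_equal(register_split(cfp, frame_stack(noisy, 0:2), 5)$shift,
               c(dy = 3, dx = -2))
  zero <- frame_stack(array(0, dim = c(40, 40, 3)), 0:2)
  expect_error(register_split(zero, zero, 3),
               class = "quadmap_analysis_error")
})

test_that("line profiles sample constants, ramps and vignettes faithfully", {
  const <- matrix(7, 30, 30)
  pr <- line_profile(const, c(15, 2), c(15, 28), width = 3)
  expect_true(all(pr$value == 7))
  expect_equal(pr$distance_mm, seq(0, 26) * 0.1)
  ramp <- matrix(seq_len(30), 30, 30, byrow = TRUE)  # value = column
  pr2 <- line_profile(ramp, c(10, 3), c(10, 27))
  expect_equal(pr2$value, seq(3, 27))
  expect_error(line_profile(const, c(5, 5), c(5, 5)),
               class = "quadmap_analysis_error")
  expect_error(line_profile(const, c(0, 5), c(5, 5)),
               class = "quadmap_config_error")
  # vignetted synthetic frame: dimmer at both mask edges than at the center
  g <- build_geometry(32, 32, "ventricle_anterior")
  ch <- channel_model(noise_sd = 0, vignette_strength = 0.4,
                      bleedthrough = identity_bleed(), quantize = FALSE)
  rec <- render_recording(g, acquisition_schedule(total_duration = 10),
                          flat_curves(), ch, seed = 1)
  frame <- rec$fret$cfp$data[, , 1]
  mid <- 16
  cols_in <- range(which(g$mask[mid, ]))
  pr3 <- line_profile(frame, c(mid, cols_in[1]), c(mid, cols_in[2]))
  n <- nrow(pr3)
  expect_lt(pr3$value[1], pr3$value[ceiling(n / 2)])
  expect_lt(pr3$value[n], pr3$value[ceiling(n / 2)])
})
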