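test_that("alignment fitting is exact on constructed configurations", {
  src <- cbind(c(1, 5, 9, 2), c(2, 3, 8, 7))
  id <- fit_alignment(src, src)
  expect_equal(id$scale, 1)
  expect_equal(id$rotation, 0)
  expect_equal(unname(id$translation), c(0, 0))
  expect_equal(id$rmse, 0)
  tf <- fit_alignment(src[1:3, ], 2 * src[1:3, ] + 5)
  expect_equal(tf$scale, 2)
  expect_equal(tf$rotation, 0)
  expect_equal(unname(tf$translation), c(5, 5))
  expect_equal(tf$rmse, 0, tolerance = 1e-12)
  expect_error(fit_alignment(cbind(c(2, 2), c(3, 3)), src[1:2, ]),
               class = "quadmap_analysis_error")
  expect_error(fit_alignment(src[1, , drop = FALSE], src[1, , drop = FALSE]),
               class = "quadmap_config_error")
})

test_that("noisy fits match the brute-force parameter-grid optimum", {
  set.seed(41)
  src <- cbind(runif(4, 0, 50), runif(4, 0, 50))
  th <- 0.22; sc <- 1.7; tr <- c(6, -3)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dst <- t(sc * R %*% t(src)) + rep(tr, each = 4) +
    matrix(rnorm(8, 0, 0.4), 4)
  fit <- fit_alignment(src, dst)
  # oracle: exhaustive scale x rotation grid with closed-form translation
  sse <- function(s, a) {
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    proj <- t(s * Rm %*% t(src))
    off <- colMeans(dst) - colMeans(proj)
    sum((t(proj) + off - t(dst))^2)
  }
  grid <- expand.grid(s = seq(1.5, 1.9, by = 5e-4),
                      a = seq(0.1, 0.35, by = 5e-4))
  errs <- mapply(sse, grid$s, grid$a)
  best <- grid[which.min(errs), ]
  expect_equal(fit$scale, best$s, tolerance = 1e-3)
  expect_equal(fit$rotation, best$a, tolerance = 1e-3)
  expect_lte(sse(fit$scale, fit$rotation), min(errs) + 1e-9)
})

test_that("transforms invert analytically", {
  set.seed(42)
  src <- cbind(runif(5, 0, 40), runif(5, 0, 40))
  dst <- cbind(runif(5, 0, 40), runif(5, 0, 40))
  tf <- fit_alignment(src, dst)
  back <- apply_alignment(invert_alignment(tf), apply_alignment(tf, src))
  expect_equal(back, src, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ROI mapping rasterizes across grids correctly", {
  roi <- as.matrix(expand.grid(row = 10:19, col = 20:29))
  same <- fit_alignment(cbind(c(1, 50), c(1, 50)), cbind(c(1, 50), c(1, 50)))
  mapped <- map_roi(roi, same, c(60, 60))
  expect_setequal(paste(mapped[, 1], mapped[, 2]),
                  paste(roi[, "row"], roi[, "col"]))
  # FRET-to-map scaling 7/100: a 100 x 100 px ROI becomes about 7 x 7 px
  big <- as.matrix(expand.grid(row = 301:400, col = 501:600))
  shrink <- fit_alignment(cbind(c(0, 1000), c(0, 1000)) * 1.0,
                          cbind(c(0, 70), c(0, 70)) * 1.0)
  small <- map_roi(big, shrink, c(100, 100))
  expect_gte(nrow(small), 36)
  expect_lte(nrow(small), 74)
  off <- fit_alignment(cbind(c(1, 9), c(1, 9)),
                       cbind(c(1001, 1009), c(1001, 1009)))
  expect_error(map_roi(roi, off, c(60, 60)),
               class = "quadmap_analysis_error")
})

test_that("ROI colocalization across camera grids preserves regional means", {
  g <- build_geometry(48, 48, "ventricle_anterior")
  rec <- render_recording(g, acquisition_schedule(total_duration = 40),
                          response_preset("ne"), clean_channels(), seed = 3)
  rm <- compute_ratio(rec$fret, 1,
                      dark_offset = rec$channels$offset[c("cfp", "yfp")])
  # pretend the FRET ROIs live on a 2x-magnified camera grid
  tf <- fit_alignment(cbind(c(2, 96, 2), c(2, 2, 96)),
                      cbind(c(1, 48, 1), c(1, 1, 48)))
  for (nm in names(g$regions)) {
    roi_hi <- which(matrix(seq_len(48 * 48) %in% g$regions[[nm]], 48, 48),
                    arr.ind = TRUE) * 2
    mapped <- map_roi(roi_hi, tf, c(48, 48))
    tr <- roi_trace(rm, quadmap:::roi_to_idx(mapped, c(48, 48)), nm)
    truth <- rec$truth$delta_fret_true[[nm]]
    expect_lt(max(abs(tr$values - truth) / truth), 0.02)
  }
})

test_that("paired t and regional summaries match hand-computed oracles", {
  same <- paired_t(c(3, 5, 8), c(3, 5, 8))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ex <- paired_t(c(1, 2, 4), c(2, 3, 3))
  expect_equal(abs(ex$t), 0.5)
  expect_equal(ex$df, 2)
  expect_equal(ex$mean_diff, -1 / 3)
  # two-tailed p by numeric integration of the t density, df = 2
  dens <- function(x) dt(x, df = 2)
  p_oracle <- 2 * integrate(dens, 0.5, Inf)$value
  expect_equal(ex$p, p_oracle, tolerance = 1e-6)
  expect_error(paired_t(1, 2), class = "quadmap_config_error")
  expect_warning(res <- paired_t(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(res$p, 0)

  s <- summarize_region(c(2, 4, 6), "RV base")
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3))
  expect_equal(s$n_hearts, 3)
  expect_true(is.na(summarize_region(5)$sem))
  expect_equal(summarize_region(rep(7, 4))$sem, 0)
  expect_error(summarize_region(numeric(0)),
               class = "quadmap_config_error")
})
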