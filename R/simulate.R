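#' Render a synthetic quad-channel recording with ground truth
#'
#' Generates CFP/YFP FRET frames interleaved with high-rate Vm/Ca bursts
#' according to an acquisition schedule, over a heart geometry, with
#' region-wise drug-response curves and a detection channel model. Every
#' quantity the analysis pipeline later estimates is also returned as
#' analytic ground truth.
#'
#' Signal model, per mask pixel: the true normalized FRET ratio
#' dFRET(t) follows the pixel's region curve; CFP fluorescence is
#' `gain * dFRET^a` and YFP is `gain * dFRET^-b`, so CFP rises and YFP
#' falls as cAMP rises and the CFP/YFP ratio equals `dFRET^(a+b)` —
#' exactly dFRET with the default `a = b = 1/2`. Each burst contains beats
#' at the scheduled heart rate; every beat activates first at the focal
#' source (onsets rounded to the sampling grid) and reaches other pixels
#' after `distance / conduction_velocity`. Action potentials and calcium
#' transients use the analytic templates ([ap_waveform()], [ca_waveform()])
#' with per-pixel APD80/CaTD50 scaled by the burst-time value of the
#' `apd_scale`/`catd_scale` curves. Vignetting attenuates fluorescence
#' radially; bleed-through mixes clean channel signals linearly; Gaussian
#' noise is added last and frames are quantized to integer counts.
#'
#' @param geometry A [build_geometry()] result.
#' @param schedule An [acquisition_schedule()].
#' @param curves A list as returned by [response_preset()]: element
#'   `delta_fret` (a single `response_curve`, optionally refined per region
#'   via `delta_fret_regions`) or a named list of per-region curves that
#'   must cover every labeled region and include a `.default` entry for
#'   unlabeled mask pixels; optional `apd_scale`, `catd_scale`,
#'   `rate_scale` curves (flat when absent).
#' @param channels A [channel_model()].
#' @param seed Integer seed fixing all randomness; identical inputs and
#'   seed give bit-identical output.
#' @param base_apd80,base_catd50 Baseline duration maps in ms: a scalar, a
#'   full `rows x cols` matrix, or `NULL` for the preset default (ventricle:
#'   APD80 graded 55 at the base to 45 at the apex, CaTD50 40; atria: 35 /
#'   30).
#' @param base_rate_bpm Baseline heart rate in bpm (default 300).
#' @param upstroke_ms,ca_rise_ms Template upstroke/rise times in ms.
#' @param first_beat_ms Focal onset of the first beat within each burst, ms.
#' @return A `quad_recording`: `fret` (a [fret_recording()]), `bursts` (per
#'   burst: `vm` and `ca` [frame_stack()]s and the burst `start_time` in s),
#'   and `truth` with `activation_time` (ms map), `apd80_true`/`catd50_true`
#'   (rows x cols x n_bursts arrays), `delta_fret_true` (per-region time
#'   series data.frame), `heart_rate_true` (realized bpm per burst),
#'   `beat_onsets` (focal, ms per burst).
#' @examples
#' g <- build_geometry(32, 32, "ventricle_anterior")
#' sched <- acquisition_schedule(total_duration = 20)
#' rec <- render_recording(g, sched, response_preset("ne"), seed = 7)
#' rec$truth$heart_rate_true
#' @export
render_recording <- function(geometry, schedule = acquisition_schedule(),
                             curves = response_preset("ne"),
                             channels = channel_model(), seed = 1,
                             base_apd80 = NULL, base_catd50 = NULL,
                             base_rate_bpm = 300,
                             upstroke_ms = 2, ca_rise_ms = 5,
                             first_beat_ms = 20) {
  stopifnot(inherits(geometry, "heart_geometry"),
            inherits(schedule, "acquisition_schedule"),
            inherits(channels, "channel_model"))
  mask <- geometry$mask
  rows <- nrow(mask); cols <- ncol(mask)
  mask_idx <- which(mask)
  delays <- activation_delays(geometry)

  # --- region grouping: group 1 = unlabeled mask pixels, then each region
  gid <- integer(rows * cols)
  gid[mask_idx] <- 1L
  rnames <- names(geometry$regions)
  for (i in seq_along(rnames)) gid[geometry$regions[[rnames[i]]]] <- i + 1L
  group_names <- c(".default", rnames)

  delta_curves <- resolve_delta_curves(curves, rnames)
  flat <- function(kind) response_curve(0, 1, kind)
  apd_curve <- curves$apd_scale %||% flat("apd_scale")
  catd_curve <- curves$catd_scale %||% flat("catd_scale")
  rate_curve <- curves$rate_scale %||% flat("rate_scale")

  apd_base <- resolve_base_map(base_apd80, geometry, "apd80")
  catd_base <- resolve_base_map(base_catd50, geometry, "catd50")

  ft <- fret_times(schedule)
  bts <- burst_times(schedule)
  burst_ms <- schedule$burst_duration * 1000
  dt_ms <- 1000 / schedule$burst_rate
  nT <- round(schedule$burst_duration * schedule$burst_rate)
  tvec <- (seq_len(nT) - 1) * dt_ms

  vig <- vignette_field(mask, channels$vignette_strength)
  bt_mat <- channels$bleedthrough
  gain <- channels$gain; offset <- channels$offset
  noise_sd <- channels$noise_sd; depth <- channels$depth

  # ground-truth dFRET per group per FRET frame
  delta_groups <- vapply(delta_curves,
                         function(cu) camp_response(ft, cu),
                         numeric(length(ft)))      # nft x ngroups
  if (is.null(dim(delta_groups)))
    delta_groups <- matrix(delta_groups, nrow = 1)

  qz <- if (channels$quantize) quantize else identity
  out <- with_seed(seed, function() {
    # ---- FRET frames ----
    cfp_arr <- array(if (channels$quantize) 0L else 0,
                     dim = c(rows, cols, length(ft)))
    yfp_arr <- cfp_arr
    for (f in seq_along(ft)) {
      dpx <- delta_groups[f, gid[mask_idx]]
      cfp_fl <- matrix(0, rows, cols)
      yfp_fl <- matrix(0, rows, cols)
      cfp_fl[mask_idx] <- gain["cfp"] * dpx ^ channels$fret_a
      yfp_fl[mask_idx] <- gain["yfp"] * dpx ^ (-channels$fret_b)
      cfp_fl <- cfp_fl * vig; yfp_fl <- yfp_fl * vig
      cfp_det <- cfp_fl + bt_mat["yfp", "cfp"] * yfp_fl
      yfp_det <- yfp_fl + bt_mat["cfp", "yfp"] * cfp_fl
      cfp_arr[, , f] <- qz(cfp_det + offset["cfp"] +
                                   gnoise(rows * cols, noise_sd["cfp"]))
      yfp_arr[, , f] <- qz(yfp_det + offset["yfp"] +
                                   gnoise(rows * cols, noise_sd["yfp"]))
    }

    # ---- Vm/Ca bursts ----
    npx <- length(mask_idx)
    delay_px <- delays[mask_idx]
    apd_px0 <- apd_base[mask_idx]
    catd_px0 <- catd_base[mask_idx]
    vig_px <- vig[mask_idx]
    bursts <- vector("list", length(bts))
    hr_true <- numeric(length(bts))
    onsets_list <- vector("list", length(bts))
    apd_true <- array(NA_real_, dim = c(rows, cols, length(bts)))
    catd_true <- array(NA_real_, dim = c(rows, cols, length(bts)))

    for (k in seq_along(bts)) {
      hr_nom <- base_rate_bpm * eval_curve(rate_curve, bts[k])
      period <- 60000 / hr_nom
      apd_k <- apd_px0 * eval_curve(apd_curve, bts[k])
      catd_k <- catd_px0 * eval_curve(catd_curve, bts[k])
      n_beats <- floor((burst_ms - 1 - first_beat_ms) / period) + 1
      onsets <- round(first_beat_ms + (seq_len(n_beats) - 1) * period)
      hr_true[k] <- if (n_beats >= 2) 60000 / mean(diff(onsets)) else NA_real_
      onsets_list[[k]] <- onsets

      span_ap <- max(template_span(apd_k, upstroke_ms, 0.2))
      span_ca <- max(template_span(catd_k, ca_rise_ms, 0.5))
      max_delay <- max(delay_px)

      vm_sig <- matrix(0, nT, npx)
      ca_sig <- matrix(0, nT, npx)
      for (o in onsets) {
        lo <- max(1L, floor(o / dt_ms) + 1L)
        hi <- min(nT, ceiling((o + max_delay +
                                 max(span_ap, span_ca)) / dt_ms) + 1L)
        if (lo > hi) next
        nwin <- hi - lo + 1L
        t_rel <- outer(tvec[lo:hi], o + delay_px, "-")
        vm_sig[lo:hi, ] <- vm_sig[lo:hi, ] +
          template_wave(t_rel, rep(apd_k, each = nwin), upstroke_ms, 0.2)
        ca_sig[lo:hi, ] <- ca_sig[lo:hi, ] +
          template_wave(t_rel, rep(catd_k, each = nwin), ca_rise_ms, 0.5)
      }

      vm_fl <- gain["vm"] * (1 + channels$vm_polarity * depth["vm"] *
                               vm_sig) * rep(vig_px, each = nT)
      ca_fl <- gain["ca"] * (1 + depth["ca"] * ca_sig) *
        rep(vig_px, each = nT)
      vm_det <- vm_fl + bt_mat["ca", "vm"] * ca_fl
      ca_det <- ca_fl + bt_mat["vm", "ca"] * vm_fl

      # scatter T x P trace matrices back into the frame grid
      flat_vm <- matrix(0, rows * cols, nT)
      flat_ca <- matrix(0, rows * cols, nT)
      flat_vm[mask_idx, ] <- t(vm_det)
      flat_ca[mask_idx, ] <- t(ca_det)
      vm_arr <- array(qz(flat_vm + offset["vm"] +
                                 gnoise(length(flat_vm), noise_sd["vm"])),
                      dim = c(rows, cols, nT))
      ca_arr <- array(qz(flat_ca + offset["ca"] +
                                 gnoise(length(flat_ca), noise_sd["ca"])),
                      dim = c(rows, cols, nT))

      atk <- matrix(NA_real_, rows, cols)
      atk[mask_idx] <- apd_k
      apd_true[, , k] <- atk
      atk[mask_idx] <- catd_k
      catd_true[, , k] <- atk

      bursts[[k]] <- list(
        vm = frame_stack(vm_arr, bts[k] + tvec / 1000,
                         geometry$pixel_pitch, "vm"),
        ca = frame_stack(ca_arr, bts[k] + tvec / 1000,
                         geometry$pixel_pitch, "ca"),
        start_time = bts[k])
    }
    list(cfp = cfp_arr, yfp = yfp_arr, bursts = bursts, hr = hr_true,
         onsets = onsets_list, apd_true = apd_true, catd_true = catd_true)
  })

  dft <- as.data.frame(delta_groups)
  names(dft) <- group_names
  npx_group <- vapply(seq_along(group_names),
                      function(i) sum(gid[mask_idx] == i), 1L)
  dft$mask_mean <- as.numeric(delta_groups %*% npx_group) / length(mask_idx)
  dft <- cbind(time = ft, dft)

  truth <- list(activation_time = delays,
                apd80_true = out$apd_true, catd50_true = out$catd_true,
                delta_fret_true = dft,
                heart_rate_true = out$hr, beat_onsets = out$onsets)

  structure(list(
    fret = fret_recording(
      frame_stack(out$cfp, ft, geometry$pixel_pitch, "cfp"),
      frame_stack(out$yfp, ft, geometry$pixel_pitch, "yfp"),
      mask),
    bursts = out$bursts, truth = truth, geometry = geometry,
    schedule = schedule, channels = channels, seed = seed),
    class = "quad_recording")
}

#' @export
print.quad_recording <- function(x, ...) {
  cat(sprintf("quad_recording: %d FRET frame pairs, %d Vm/Ca bursts, %d x %d px (seed %d)\n",
              n_frames(x$fret$cfp), length(x$bursts),
              nrow(x$geometry$mask), ncol(x$geometry$mask), x$seed))
  invisible(x)
}

resolve_delta_curves <- function(curves, region_names) {
  df <- curves$delta_fret
  if (inherits(df, "response_curve")) {
    reg <- curves$delta_fret_regions %||% list()
    out <- c(list(df),
             lapply(region_names, function(nm) reg[[nm]] %||% df))
  } else if (is.list(df)) {
    missing <- setdiff(region_names, names(df))
    if (length(missing))
      config_error(sprintf("no delta_fret curve for region(s): %s",
                           paste(missing, collapse = ", ")))
    if (is.null(df[[".default"]]))
      config_error("per-region delta_fret list must include a '.default' curve")
    out <- c(list(df[[".default"]]), df[region_names])
  } else {
    config_error("curves$delta_fret must be a response_curve or a named list")
  }
  lapply(out, function(cu) {
    if (!inherits(cu, "response_curve") || cu$applies_to != "delta_fret")
      config_error("delta_fret entries must be delta_fret response curves")
    cu
  })
}

resolve_base_map <- function(x, geometry, kind) {
  mask <- geometry$mask
  rows <- nrow(mask); cols <- ncol(mask)
  if (is.null(x)) {
    if (geometry$preset == "ventricle_anterior") {
      if (kind == "apd80") {
        rr <- range(which(rowSums(mask) > 0))
        grad <- 55 - 10 * (seq_len(rows) - rr[1]) / max(1, diff(rr))
        x <- matrix(grad, rows, cols)
      } else x <- 40
    } else {
      x <- if (kind == "apd80") 35 else 30
    }
  }
  if (length(x) == 1) x <- matrix(x, rows, cols)
  if (!all(dim(x) == c(rows, cols)))
    config_error(sprintf("base %s map must be %d x %d", kind, rows, cols))
  if (any(x[mask] <= 0))
    config_error(sprintf("base %s must be positive inside the mask", kind))
  x
}

gnoise <- function(n, sd) if (sd > 0) rnorm(n, 0, sd) else 0

quantize <- function(x) {
  storage.mode(x) <- "double"
  x <- round(x)
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  storage.mode(x) <- "integer"
  x
}
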