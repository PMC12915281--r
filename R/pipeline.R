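#' Validate a pipeline run configuration
#'
#' Configurations are plain lists (or JSON files) describing either a
#' simulated run (`mode = "simulate"`: geometry, drug preset, channel
#' noise) or a file-based run (`mode = "files"`: per-channel stack paths).
#' The structural rules are published in
#' `system.file("extdata", "config-schema.json", package = "quadmap")`;
#' validation happens before any computation and reports every violation.
#'
#' @param config A list or path to a JSON config file.
#' @return The validated config list (with defaults filled), invisibly
#'   classed `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      config_error(sprintf("no such config file: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) config_error("config must be a list or JSON path")
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  config$mode <- config$mode %||% "simulate"
  need(config$mode %in% c("simulate", "files"),
       "mode must be 'simulate' or 'files'")
  config$seed <- config$seed %||% 1L
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "seed must be a single integer")
  config$stimulus_onset <- config$stimulus_onset %||% 0
  need(is.numeric(config$stimulus_onset), "stimulus_onset must be numeric (s)")

  sch <- config$schedule %||% list()
  need(is.list(sch), "schedule must be a list of schedule fields")
  config$schedule <- sch

  if (identical(config$mode, "simulate")) {
    g <- config$geometry %||% list()
    g$rows <- g$rows %||% 64L; g$cols <- g$cols %||% 64L
    g$preset <- g$preset %||% "ventricle_anterior"
    need(is.numeric(g$rows) && is.numeric(g$cols),
         "geometry rows/cols must be numeric")
    config$geometry <- g
    config$drug <- config$drug %||% "ne"
    need(config$drug %in% c("ne", "ach", "tyramine"),
         "drug must be one of ne, ach, tyramine")
  } else {
    p <- config$paths %||% list()
    for (ch in c("cfp", "yfp", "mask")) {
      need(!is.null(p[[ch]]), sprintf("paths$%s is required", ch))
      if (!is.null(p[[ch]]))
        need(file.exists(p[[ch]]),
             sprintf("paths$%s does not exist: %s", ch, p[[ch]]))
    }
    for (ch in c("vm", "ca"))
      need(!is.null(p[[ch]]),
           sprintf("missing %s channel: paths$%s is required", ch, ch))
    config$paths <- p
  }
  config$n_beats <- config$n_beats %||% 10L
  config$polarity <- config$polarity %||% list(vm = -1, ca = 1)
  need(config$polarity$vm %in% c(-1, 1) && config$polarity$ca %in% c(-1, 1),
       "polarity entries must be +1 or -1")
  if (length(problems))
    config_error(paste0("invalid config:\n  - ",
                        paste(problems, collapse = "\n  - ")))
  class(config) <- c("run_config", "list")
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain <- plain[order(names(plain))]
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end interleaved FRET / optical-mapping pipeline
#'
#' Orchestrates the full workflow: obtain the recording (simulated with
#' ground truth, or read from per-channel TIFF stacks), compute the
#' pixel-wise dFRET movie and ROI time courses, analyze every Vm/Ca burst
#' into APD80 and CaTD50 maps plus heart rate, and colocalize the ROI set
#' across modalities. Each burst is paired with the immediately preceding
#' FRET frame (the hardware trigger order). Deterministic given config and
#' seed.
#'
#' @param config A [run_config()] (or list / JSON path accepted by it).
#' @param out_dir Optional directory; when given, summary tables are
#'   written as CSV (each embedding the config hash) and maps as TIFF.
#' @return A result bundle: `summary` (one row per schedule slot: time,
#'   whole-mask dFRET, APD80, CaTD50, heart rate), `roi_summary` (tidy
#'   rows: slot time, region, metric, value), `ratio` (the
#'   [compute_ratio()] movie), `traces` (per-ROI `delta_fret_trace`s),
#'   `maps` (per burst: `apd80`, `catd50` [duration_map()]s), `truth`
#'   (simulate mode only), `config`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- run_config(config)
  hash <- config_hash(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      qm_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "quadmap_pipeline_error"))
  }

  sched <- stage("schedule",
                 do.call(acquisition_schedule, config$schedule))
  truth <- NULL
  if (identical(config$mode, "simulate")) {
    rec <- stage("simulate", {
      geom <- build_geometry(config$geometry$rows, config$geometry$cols,
                             config$geometry$preset)
      render_recording(geom, sched, response_preset(config$drug),
                       channel_model(), seed = config$seed)
    })
    fret <- rec$fret
    bursts <- rec$bursts
    truth <- rec$truth
    rois <- rec$geometry$regions
    offset <- rec$channels$offset[c("cfp", "yfp")]
  } else {
    p <- config$paths
    fret <- stage("read", {
      mask_stack <- read_stack(p$mask)
      fret_recording(read_stack(p$cfp), read_stack(p$yfp),
                     mask_stack$data[, , 1] > 0)
    })
    bursts <- stage("read", lapply(seq_along(p$vm), function(k) {
      list(vm = read_stack(p$vm[[k]]), ca = read_stack(p$ca[[k]]),
           start_time = read_stack(p$vm[[k]])$times[1])
    }))
    rois <- if (!is.null(config$roi_file))
      lapply(read_roi_json(config$roi_file, dim(fret$mask)),
             roi_to_idx, shape = dim(fret$mask))
    else list()
    offset <- config$yfp_offset %||% 0
  }

  baseline_window <- config$baseline_window %||%
    which(fret$cfp$times <= config$stimulus_onset)
  if (!length(baseline_window)) baseline_window <- 1L

  ratio <- stage("fret", compute_ratio(fret, baseline_window,
                                       yfp_floor = 5 * offset[[length(offset)]],
                                       dark_offset = offset))
  traces <- stage("fret", c(
    list(mask = roi_trace(ratio, ratio$mask, "mask")),
    stats::setNames(lapply(names(rois), function(nm)
      roi_trace(ratio, roi_to_idx_any(rois[[nm]], dim(fret$mask)), nm)),
      names(rois))))

  maps <- stage("electro", lapply(bursts, function(bu) {
    list(start_time = bu$start_time,
         apd80 = duration_map(bu$vm, ratio$mask, "apd80",
                              n_beats = config$n_beats,
                              polarity = config$polarity$vm),
         catd50 = duration_map(bu$ca, ratio$mask, "catd50",
                               n_beats = config$n_beats,
                               polarity = config$polarity$ca))
  }))

  slot_time <- vapply(bursts, function(b) b$start_time, 1)
  fret_slot <- vapply(slot_time, function(tt) {
    idx <- which(fret$cfp$times <= tt)
    idx[length(idx)]                     # immediately preceding FRET frame
  }, 1L)
  summary <- data.frame(
    time = fret$cfp$times[fret_slot],
    delta_fret = traces$mask$values[fret_slot],
    apd80 = vapply(maps, function(m) mean(m$apd80$values, na.rm = TRUE), 1),
    catd50 = vapply(maps, function(m) mean(m$catd50$values, na.rm = TRUE), 1),
    heart_rate = vapply(maps, function(m) m$apd80$heart_rate, 1),
    config_hash = hash)

  roi_summary <- do.call(rbind, lapply(names(rois), function(nm) {
    idx <- roi_to_idx_any(rois[[nm]], dim(fret$mask))
    idx <- intersect(idx, which(ratio$mask))
    do.call(rbind, lapply(seq_along(maps), function(k) data.frame(
      time = summary$time[k], region = nm,
      metric = c("delta_fret", "apd80", "catd50"),
      value = c(traces[[nm]]$values[fret_slot[k]],
                mean(maps[[k]]$apd80$values[idx], na.rm = TRUE),
                mean(maps[[k]]$catd50$values[idx], na.rm = TRUE)),
      config_hash = hash)))
  }))

  bundle <- list(summary = summary, roi_summary = roi_summary,
                 ratio = ratio, traces = traces, maps = maps,
                 truth = truth, config = config, config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    if (!is.null(roi_summary))
      write.csv(roi_summary, file.path(out_dir, "roi_summary.csv"),
                row.names = FALSE)
    for (k in seq_along(maps)) {
      write_stack(frame_stack(maps[[k]]$apd80$values, maps[[k]]$start_time,
                              fret$cfp$pixel_pitch, "apd80"),
                  file.path(out_dir, sprintf("apd80_%03d.tif", k)),
                  "float32")
      write_stack(frame_stack(maps[[k]]$catd50$values, maps[[k]]$start_time,
                              fret$cfp$pixel_pitch, "catd50"),
                  file.path(out_dir, sprintf("catd50_%03d.tif", k)),
                  "float32")
    }
  }
  bundle
}

roi_to_idx_any <- function(roi, shape) {
  if (is.matrix(roi) && ncol(roi) == 2) roi_to_idx(roi, shape)
  else as.integer(roi)
}

#' Write a simulated recording to disk
#'
#' Renders a recording with [render_recording()] and writes per-channel
#' 16-bit multi-page TIFF stacks, the mask, a ground-truth/metadata JSON
#' sidecar (schedule, regions, seed, realized heart rates) and the config.
#'
#' @param config A simulate-mode [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir) {
  config <- run_config(config)
  if (!identical(config$mode, "simulate"))
    config_error("simulate_to_dir requires a simulate-mode config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- do.call(acquisition_schedule, config$schedule)
  geom <- build_geometry(config$geometry$rows, config$geometry$cols,
                         config$geometry$preset)
  rec <- render_recording(geom, sched, response_preset(config$drug),
                          channel_model(), seed = config$seed)
  write_stack(rec$fret$cfp, file.path(out_dir, "cfp.tif"))
  write_stack(rec$fret$yfp, file.path(out_dir, "yfp.tif"))
  write_stack(frame_stack(array(as.integer(rec$fret$mask),
                                dim = c(dim(rec$fret$mask), 1L)),
                          0, geom$pixel_pitch, "mask"),
              file.path(out_dir, "mask.tif"))
  for (k in seq_along(rec$bursts)) {
    write_stack(rec$bursts[[k]]$vm,
                file.path(out_dir, sprintf("burst_%03d_vm.tif", k)))
    write_stack(rec$bursts[[k]]$ca,
                file.path(out_dir, sprintf("burst_%03d_ca.tif", k)))
  }
  meta <- list(seed = config$seed, drug = config$drug,
               schedule = unclass(sched),
               regions = lapply(geom$regions, function(i) i - 1L),
               focal_source = geom$focal_source - 1L,
               heart_rate_true = rec$truth$heart_rate_true,
               delta_fret_true = rec$truth$delta_fret_true)
  jsonlite::write_json(meta, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
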