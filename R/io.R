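#' Read and write frame stacks as multi-page TIFF
#'
#' Stacks are stored as multi-page TIFF with a JSON sidecar
#' (`<path>.json`) carrying timestamps, pixel pitch, channel name and the
#' stored dtype. 16-bit unsigned stacks (`dtype = "uint16"`) round-trip
#' bit-exactly; floating-point maps (`dtype = "float32"`) are normalized to
#' the unit range with scale/offset recorded in the sidecar and round-trip
#' to within 32-bit float precision. If no sidecar is present, `times` (or
#' a constant sampling interval `dt`) must be supplied.
#'
#' @param stack A [frame_stack()].
#' @param path TIFF file path.
#' @param dtype `"uint16"` (integer counts in 0..65535) or `"float32"`.
#' @return `write_stack()`: `path`, invisibly. `read_stack()`: a
#'   [frame_stack()].
#' @export
write_stack <- function(stack, path, dtype = c("uint16", "float32")) {
  stopifnot(inherits(stack, "frame_stack"))
  dtype <- match.arg(dtype)
  x <- stack$data * 1.0
  meta <- list(times = stack$times, pixel_pitch_mm = stack$pixel_pitch,
               channel = stack$channel, dtype = dtype)
  if (dtype == "uint16") {
    if (any(x < 0 | x > 65535, na.rm = TRUE) ||
        any(x != round(x), na.rm = TRUE))
      format_error("uint16 stacks require integer counts in 0..65535")
    x[is.na(x)] <- 0
    pages <- lapply(seq_len(dim(x)[3]), function(f) x[, , f] / 65535)
    bits <- 16L
  } else {
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    scale <- if (hi > lo) hi - lo else 1
    meta$float_offset <- lo
    meta$float_scale <- scale
    x[is.na(x)] <- lo
    pages <- lapply(seq_len(dim(x)[3]), function(f) (x[, , f] - lo) / scale)
    bits <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param expected_dtype Optionally assert the stored dtype.
#' @param times,dt Timestamps (s) or constant sampling interval (s), used
#'   when no sidecar exists.
#' @export
read_stack <- function(path, expected_dtype = NULL, times = NULL, dt = NULL) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else list()
  dtype <- meta$dtype %||% "uint16"
  if (!is.null(expected_dtype) && !identical(dtype, expected_dtype))
    format_error(sprintf("expected dtype %s but %s holds %s",
                         expected_dtype, path, dtype))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE,
                                   as.is = dtype == "uint16"),
                    error = function(e)
                      format_error(sprintf("cannot read TIFF %s: %s",
                                           path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (is.null(dim(pages[[i]])) || !all(dim(pages[[i]])[1:2] == d1[1:2]))
      format_error(sprintf("corrupt or ragged TIFF page %d in %s", i, path))
  }
  x <- array(unlist(pages), dim = c(d1[1], d1[2], length(pages)))
  if (dtype == "uint16") {
    storage.mode(x) <- "integer"
  } else {
    x <- x * (meta$float_scale %||% 1) + (meta$float_offset %||% 0)
  }
  tms <- meta$times %||% times
  if (is.null(tms) && !is.null(dt)) tms <- (seq_along(pages) - 1) * dt
  if (is.null(tms))
    format_error(sprintf("missing timestamps for %s: no sidecar and no times/dt given", path))
  if (length(tms) != length(pages))
    format_error(sprintf("%d timestamps for %d pages in %s",
                         length(tms), length(pages), path))
  frame_stack(x, tms, meta$pixel_pitch_mm %||% 0.1, meta$channel)
}

#' Read and write ROI definitions as JSON
#'
#' ROI files hold a list of named ROIs, each either an explicit pixel list
#' or a polygon, with 0-based `(row, col)` coordinates on disk (converted
#' to the package's 1-based in-memory convention).
#'
#' @param path JSON file path.
#' @param shape `c(rows, cols)` of the grid the ROIs refer to.
#' @return A named list of k x 2 `(row, col)` pixel coordinate matrices.
#' @export
read_roi_json <- function(path, shape) {
  if (!file.exists(path)) format_error(sprintf("no such ROI file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (roi in raw$rois %||% raw) {
    label <- roi$label %||% sprintf("roi%d", length(out) + 1)
    if (!is.null(roi$pixels)) {
      px <- matrix(as.numeric(unlist(roi$pixels)), ncol = 2, byrow = TRUE) + 1
    } else if (!is.null(roi$polygon)) {
      poly <- matrix(as.numeric(unlist(roi$polygon)), ncol = 2,
                     byrow = TRUE) + 1
      cand <- as.matrix(expand.grid(row = seq_len(shape[1]),
                                    col = seq_len(shape[2])))
      px <- cand[mgcv::in.out(poly, cand * 1.0), , drop = FALSE]
    } else {
      format_error(sprintf("ROI '%s' has neither pixels nor polygon", label))
    }
    keep <- px[, 1] >= 1 & px[, 1] <= shape[1] &
      px[, 2] >= 1 & px[, 2] <= shape[2]
    out[[label]] <- px[keep, , drop = FALSE]
  }
  out
}

#' @rdname read_roi_json
#' @param rois Named list of k x 2 `(row, col)` matrices (1-based).
#' @export
write_roi_json <- function(rois, path) {
  payload <- list(rois = lapply(names(rois), function(nm) {
    list(label = nm,
         pixels = unname(apply(rois[[nm]] - 1, 1, as.numeric,
                               simplify = FALSE)))
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

roi_to_idx <- function(roi, shape) {
  if (is.logical(roi)) return(which(roi))
  roi <- matrix(as.integer(round(as.matrix(roi))), ncol = 2)
  as.integer((roi[, 2] - 1) * shape[1] + roi[, 1])
}
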