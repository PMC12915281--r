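#' Least-squares similarity transform from fiducial point pairs
#'
#' Fits the 4-parameter similarity transform (uniform scale, rotation,
#' translation) mapping source fiducial coordinates onto target
#' coordinates, minimizing the sum of squared residuals. The two camera
#' paths share optics and differ essentially in magnification and offset,
#' so a similarity (rather than a full affine) is fitted; reflection is
#' excluded. Internally the closed-form complex least-squares solution is
#' used: with points as `row + 1i * col`, the optimal `a, b` of
#' `z -> a z + b` are linear least squares, `scale = |a|`,
#' `rotation = Arg(a)`.
#'
#' @param src_points,dst_points n x 2 matrices of `(row, col)` coordinates,
#'   n >= 2, same order.
#' @return A `similarity_transform`: `scale`, `rotation` (radians),
#'   `translation` `c(dy, dx)`, `rmse` (pixels).
#' @export
fit_alignment <- function(src_points, dst_points) {
  src_points <- as.matrix(src_points); dst_points <- as.matrix(dst_points)
  if (!all(dim(src_points) == dim(dst_points)) || ncol(src_points) != 2 ||
      nrow(src_points) < 2)
    config_error("need >= 2 (row, col) point pairs of equal count")
  zs <- complex(real = src_points[, 1], imaginary = src_points[, 2])
  zd <- complex(real = dst_points[, 1], imaginary = dst_points[, 2])
  zsc <- zs - mean(zs); zdc <- zd - mean(zd)
  denom <- sum(Mod(zsc)^2)
  if (denom == 0)
    analysis_error("degenerate configuration: source fiducials coincide")
  a <- sum(Conj(zsc) * zdc) / denom
  b <- mean(zd) - a * mean(zs)
  resid <- Mod(a * zs + b - zd)
  structure(list(scale = Mod(a), rotation = Arg(a),
                 translation = c(dy = Re(b), dx = Im(b)),
                 rmse = sqrt(mean(resid^2))),
            class = "similarity_transform")
}

#' @rdname fit_alignment
#' @param transform A `similarity_transform`.
#' @param points n x 2 matrix of `(row, col)` coordinates.
#' @return `apply_alignment()`: the transformed n x 2 coordinates;
#'   `invert_alignment()`: the analytic inverse transform.
#' @export
apply_alignment <- function(transform, points) {
  stopifnot(inherits(transform, "similarity_transform"))
  points <- matrix(as.numeric(points), ncol = 2)
  a <- complex(modulus = transform$scale, argument = transform$rotation)
  z <- a * complex(real = points[, 1], imaginary = points[, 2]) +
    complex(real = transform$translation[1],
            imaginary = transform$translation[2])
  cbind(Re(z), Im(z))
}

#' @rdname fit_alignment
#' @export
invert_alignment <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  a <- complex(modulus = transform$scale, argument = transform$rotation)
  b <- complex(real = transform$translation[1],
               imaginary = transform$translation[2])
  ai <- 1 / a; bi <- -b / a
  structure(list(scale = Mod(ai), rotation = Arg(ai),
                 translation = c(dy = Re(bi), dx = Im(bi)),
                 rmse = transform$rmse),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.4f, rotation %.4f rad, translation (%.2f, %.2f), rmse %.3g px\n",
              x$scale, x$rotation, x$translation[1], x$translation[2],
              x$rmse))
  invisible(x)
}

#' Map an ROI from one camera grid to another
#'
#' Transforms the ROI's pixel centers with a fitted alignment and
#' rasterizes the result on the target grid: a target pixel is included
#' when its center lies inside the convex hull of the transformed ROI
#' points (pixel-center inclusion). Each transformed point's nearest target
#' pixel is also included so that very small ROIs survive rasterization.
#'
#' @param roi Logical matrix on the source grid, or a k x 2 matrix of
#'   `(row, col)` pixel coordinates.
#' @param transform A [fit_alignment()] result mapping source to target
#'   coordinates.
#' @param target_shape `c(rows, cols)` of the target grid.
#' @return k x 2 matrix of `(row, col)` target pixel coordinates.
#' @export
map_roi <- function(roi, transform, target_shape) {
  if (is.logical(roi)) roi <- which(roi, arr.ind = TRUE)
  roi <- matrix(as.numeric(as.matrix(roi)), ncol = 2)
  if (!nrow(roi)) analysis_error("empty ROI")
  pts <- apply_alignment(transform, roi)
  rows <- target_shape[1]; cols <- target_shape[2]
  sel <- matrix(FALSE, rows, cols)
  near <- cbind(round(pts[, 1]), round(pts[, 2]))
  ok <- near[, 1] >= 1 & near[, 1] <= rows & near[, 2] >= 1 & near[, 2] <= cols
  sel[near[ok, , drop = FALSE]] <- TRUE
  hull <- unique(pts)
  if (nrow(hull) >= 3) {
    h <- grDevices::chull(hull)
    if (length(h) >= 3) {
      poly <- hull[h, , drop = FALSE]
      cand <- as.matrix(expand.grid(
        row = max(1, floor(min(poly[, 1]))):min(rows, ceiling(max(poly[, 1]))),
        col = max(1, floor(min(poly[, 2]))):min(cols, ceiling(max(poly[, 2])))))
      if (nrow(cand))
        sel[cand[mgcv::in.out(poly, cand * 1.0), , drop = FALSE]] <- TRUE
    }
  }
  out <- which(sel, arr.ind = TRUE)
  if (!nrow(out))
    analysis_error("ROI maps entirely outside the target grid")
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

#' Paired two-tailed Student's t-test
#'
#' Classical paired t with `df = n - 1` and a two-tailed p-value, used for
#' regional comparisons across hearts. With identical inputs `t = 0,
#' p = 1`; zero-variance nonzero differences give `p = 0` (limit) with a
#' warning.
#'
#' @param values_a,values_b Per-heart paired values, equal length n >= 2.
#' @return A list: `t`, `df`, `p`, `mean_diff` (mean of `values_a -
#'   values_b`).
#' @export
paired_t <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) config_error("paired samples must have equal length")
  n <- length(a)
  if (n < 2) config_error("paired t-test needs n >= 2")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    warning("zero-variance nonzero differences; p reported as limit 0")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Regional summary: mean and SEM across hearts
#'
#' @param per_heart_values One value per heart.
#' @param region Region name.
#' @return A `regional_summary`: `region`, `per_heart_values`, `mean`,
#'   `sem` (sample SD / sqrt(n); `NA` at n = 1), `n_hearts`.
#' @export
summarize_region <- function(per_heart_values, region = "region") {
  v <- as.numeric(per_heart_values)
  if (!length(v)) config_error("no values to summarize")
  structure(list(region = region, per_heart_values = v, mean = mean(v),
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else
                   NA_real_,
                 n_hearts = length(v)),
            class = "regional_summary")
}

#' @export
print.regional_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (mean +/- SEM, N = %d hearts)\n",
              x$region, x$mean, x$sem, x$n_hearts))
  invisible(x)
}
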