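#' Compare two dFRET traces with the Kolmogorov-Smirnov test
#'
#' Used to verify spectral separation: dFRET traces acquired under
#' different dye loadings should be statistically indistinguishable. With
#' `mode = "values"` the two-sample KS statistic compares the value
#' distributions of the two traces; with `mode = "paired_difference"` a
#' two-sample KS compares the time-paired differences `a - b` against their
#' negation (a symmetry-about-zero test; traces must then have equal
#' length). The p-value is asymptotic (Kolmogorov distribution).
#'
#' @param trace_a,trace_b Numeric dFRET series (or `delta_fret_trace`
#'   objects, whose `values` are used).
#' @param mode `"values"` or `"paired_difference"`.
#' @return A `comparison_result`: `statistic` (KS D), `p_value`, `n_a`,
#'   `n_b`, `mode`.
#' @export
ks_compare <- function(trace_a, trace_b,
                       mode = c("values", "paired_difference")) {
  mode <- match.arg(mode)
  a <- if (inherits(trace_a, "delta_fret_trace")) trace_a$values else
    as.numeric(trace_a)
  b <- if (inherits(trace_b, "delta_fret_trace")) trace_b$values else
    as.numeric(trace_b)
  if (length(a) < 3 || length(b) < 3)
    analysis_error("both series must have length >= 3")
  if (mode == "values") {
    ks <- suppressWarnings(ks.test(a, b, exact = FALSE))
  } else {
    if (length(a) != length(b))
      analysis_error("paired_difference mode requires equal-length traces")
    d <- a - b
    ks <- suppressWarnings(ks.test(d, -d, exact = FALSE))
  }
  structure(list(statistic = unname(ks$statistic),
                 p_value = unname(ks$p.value),
                 n_a = length(a), n_b = length(b), mode = mode),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("KS comparison (%s): D = %.4f, p = %.3g (n = %d, %d)\n",
              x$mode, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Channel bleed-through fraction
#'
#' Quantifies contamination of one detection channel by another
#' fluorophore's signal (e.g. the calcium dye's emission appearing in the
#' Vm channel) as the least-squares slope of the target trace on the source
#' trace, clipped to `[0, 1]`. Both traces must be time-aligned and
#' baseline-corrected so the slope reflects the mixed deflection rather
#' than DC offsets.
#'
#' @param source_trace Baseline-corrected source-channel series (e.g. Ca).
#' @param target_trace Baseline-corrected target-channel series (e.g. Vm),
#'   same length.
#' @return The bleed-through fraction in `[0, 1]`.
#' @export
bleedthrough_fraction <- function(source_trace, target_trace) {
  s <- as.numeric(source_trace); t <- as.numeric(target_trace)
  if (length(s) != length(t))
    analysis_error("source and target traces must be equal length")
  vs <- stats::var(s)
  if (!is.finite(vs) || vs == 0)
    analysis_error("source trace has zero variance")
  slope <- stats::cov(s, t) / vs
  min(max(slope, 0), 1)
}
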