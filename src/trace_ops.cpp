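#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window extreme (monotonic deque), centered window of `w` samples
// (w odd), clipped at the edges. Grayscale erosion (min) / dilation (max)
// with a flat structuring element.
static void run_extreme(const double* x, int n, int w, bool take_min,
                        double* out) {
  int h = w / 2;
  std::deque<int> dq;
  for (int i = 0; i < n + h; ++i) {
    if (i < n) {
      while (!dq.empty() &&
             (take_min ? x[dq.back()] >= x[i] : x[dq.back()] <= x[i]))
        dq.pop_back();
      dq.push_back(i);
    }
    int center = i - h;
    if (center >= 0) {
      while (!dq.empty() && dq.front() < center - h) dq.pop_front();
      out[center] = x[dq.front()];
    }
  }
}

// [[Rcpp::export]]
NumericVector run_min_filter(NumericVector x, int window) {
  if (window < 1) stop("window must be >= 1");
  if (window % 2 == 0) window += 1;
  NumericVector out(x.size());
  run_extreme(x.begin(), x.size(), window, true, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector run_max_filter(NumericVector x, int window) {
  if (window < 1) stop("window must be >= 1");
  if (window % 2 == 0) window += 1;
  NumericVector out(x.size());
  run_extreme(x.begin(), x.size(), window, false, out.begin());
  return out;
}

// Morphological opening (erosion then dilation) applied to each column of
// a T x P trace matrix.
// [[Rcpp::export]]
NumericMatrix morph_open_cols(NumericMatrix x, int window) {
  if (window < 3) stop("structuring element must span at least 3 samples");
  if (window % 2 == 0) window += 1;
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  std::vector<double> tmp(n);
  for (int j = 0; j < p; ++j) {
    run_extreme(&x(0, j), n, window, true, tmp.data());
    run_extreme(tmp.data(), n, window, false, &out(0, j));
  }
  return out;
}

// Per-pixel, per-beat activation sample and duration for a T x P matrix of
// baseline-corrected, polarity-normalized traces. Beat windows are 0-based
// [start, end) sample ranges. Activation is the earliest maximum forward
// difference in the window; the diastolic baseline is the mean of
// `base_pre` samples preceding activation; duration runs from activation
// to the first post-peak linear-interpolated crossing of
// peak - level * (peak - baseline) after which the trace stays at or below
// the threshold for `hold` consecutive samples (rejects single-sample
// noise excursions). With `refine` the activation sample is adjusted by the
// partial forward difference preceding the first maximal one, which equals
// the sub-sample onset fraction of a linear upstroke. Missing values where
// undefined.
// [[Rcpp::export]]
List beat_durations_cols(NumericMatrix traces, IntegerVector win_start,
                         IntegerVector win_end, double level,
                         int base_pre, double dt, int hold = 3,
                         bool refine = true) {
  int n = traces.nrow(), p = traces.ncol(), nb = win_start.size();
  NumericMatrix dur(nb, p), act(nb, p);
  std::fill(dur.begin(), dur.end(), NA_REAL);
  std::fill(act.begin(), act.end(), NA_REAL);
  for (int j = 0; j < p; ++j) {
    const double* x = &traces(0, j);
    for (int b = 0; b < nb; ++b) {
      int s = win_start[b], e = win_end[b];
      if (s < 0 || e > n || e - s < 3) continue;
      // activation: earliest maximum forward difference; differences within
      // a relative 1e-9 of the maximum count as ties (a linear upstroke has
      // an exactly flat derivative up to floating-point jitter)
      int k = -1;
      double dmax = 0.0;
      for (int i = s; i < e - 1; ++i) {
        double d = x[i + 1] - x[i];
        if (d > dmax) { dmax = d; k = i; }
      }
      if (k < 0 || dmax <= 0.0) continue;
      for (int i = s; i < k; ++i) {
        double d = x[i + 1] - x[i];
        if (d >= dmax * (1.0 - 1e-9)) { k = i; break; }
      }
      double act_t = k;
      if (refine && k > s) {
        double frac = (x[k] - x[k - 1]) / dmax;
        if (frac > 0.0 && frac < 1.0) act_t = k - frac;
      }
      act(b, j) = act_t;
      // diastolic baseline: mean of base_pre samples before activation
      int j0 = std::max(s, k - base_pre);
      double base;
      if (k > j0) {
        double acc = 0.0;
        for (int i = j0; i < k; ++i) acc += x[i];
        base = acc / (k - j0);
      } else {
        base = x[k];
      }
      // peak after activation, earliest tie
      int m = k;
      double pk = x[k];
      for (int i = k + 1; i < e; ++i)
        if (x[i] > pk) { pk = x[i]; m = i; }
      double ampl = pk - base;
      if (ampl <= 0.0) continue;
      double thr = pk - level * ampl;
      for (int i = m + 1; i < e; ++i) {
        if (x[i] <= thr) {
          bool sustained = true;
          for (int q = i + 1; q < std::min(i + hold, e); ++q)
            if (x[q] > thr) { sustained = false; break; }
          if (!sustained) continue;
          double denom = x[i - 1] - x[i];
          double cross = (denom > 0.0)
            ? (i - 1) + (x[i - 1] - thr) / denom : (double)i;
          dur(b, j) = (cross - act_t) * dt;
          break;
        }
      }
    }
  }
  return List::create(_["durations"] = dur, _["activation"] = act);
}
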