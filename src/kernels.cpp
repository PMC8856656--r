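#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// uniform integer in {0, ..., n-1} from R's RNG stream
static inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
IntegerVector cpp_shift_exceedance(NumericVector x, int n_shifts) {
  const int L = x.size();
  IntegerVector counts(L);
  std::vector<int> cnt(L, 0);
  for (int s_i = 0; s_i < n_shifts; ++s_i) {
    // shift drawn from {1, ..., L-1}: shift 0 would compare the trace to itself
    int s = 1 + runif_int(L - 1);
    // shifted[k] = x[(k - s) mod L]; strict exceedance only
    int j = L - s; // (0 - s) mod L
    for (int k = 0; k < L; ++k) {
      if (x[k] > x[j]) ++cnt[k];
      if (++j == L) j = 0;
    }
  }
  for (int k = 0; k < L; ++k) counts[k] = cnt[k];
  return counts;
}

// counts of exceedances over ALL L-1 distinct circular shifts (used by
// percent-scaled comparisons; the unit-test oracle re-implements this in R)
// [[Rcpp::export]]
IntegerVector cpp_exhaustive_exceedance(NumericVector x) {
  const int L = x.size();
  IntegerVector counts(L);
  std::vector<int> cnt(L, 0);
  for (int s = 1; s < L; ++s) {
    int j = L - s;
    for (int k = 0; k < L; ++k) {
      if (x[k] > x[j]) ++cnt[k];
      if (++j == L) j = 0;
    }
  }
  for (int k = 0; k < L; ++k) counts[k] = cnt[k];
  return counts;
}

// run_starts[k] = TRUE iff x[k..k+min_run-1] are all above `thresh` (strict)
// [[Rcpp::export]]
LogicalVector cpp_run_starts(NumericVector x, double thresh, int min_run) {
  const int L = x.size();
  LogicalVector out(L);
  int streak = 0;
  for (int k = L - 1; k >= 0; --k) {
    streak = (x[k] > thresh) ? streak + 1 : 0;
    out[k] = (streak >= min_run);
  }
  return out;
}

// window_profile[k] = TRUE iff a run of >= min_run frames above thresh lies
// entirely inside the win_frames-long window starting at frame k (0-based).
// Length of the result: L - win_frames + 1.
// [[Rcpp::export]]
LogicalVector cpp_window_profile(NumericVector x, double thresh, int min_run,
                                 int win_frames) {
  const int L = x.size();
  if (win_frames > L) stop("window longer than trace");
  LogicalVector rs = cpp_run_starts(x, thresh, min_run);
  const int n_out = L - win_frames + 1;
  const int span = win_frames - min_run; // run start may sit at k .. k+span
  LogicalVector out(n_out);
  if (span < 0) { std::fill(out.begin(), out.end(), false); return out; }
  // prefix counts of run starts
  std::vector<int> pc(L + 1, 0);
  for (int k = 0; k < L; ++k) pc[k + 1] = pc[k] + (rs[k] ? 1 : 0);
  for (int k = 0; k < n_out; ++k) out[k] = (pc[k + span + 1] - pc[k]) > 0;
  return out;
}

static double quantile7(std::vector<double> &buf, double p) {
  const int n = buf.size();
  if (n == 1) return buf[0];
  double h = p * (n - 1);
  int i0 = (int)std::floor(h);
  if (i0 > n - 2) i0 = n - 2;
  std::nth_element(buf.begin(), buf.begin() + i0, buf.end());
  double v0 = buf[i0];
  double v1 = *std::min_element(buf.begin() + i0 + 1, buf.end());
  return v0 + (h - i0) * (v1 - v0);
}

// Iterative percentile baseline: running p-quantile of the inactive frames
// over sliding windows of `width` centred every `step` frames (linear
// interpolation between centres), frames > f0 + 2*robust-SD flagged active,
// repeat until the flagged set stabilises (within tol_frac of frames) or
// max_iter passes.
// [[Rcpp::export]]
NumericVector cpp_percentile_f0(NumericVector x, int width, int step,
                                double p, int min_keep, int max_iter,
                                double tol_frac) {
  const int L = x.size();
  NumericVector f0(L);
  std::vector<char> masked(L, 0);
  std::vector<double> buf, centres, values, resid_s;
  buf.reserve(width);
  // window centres every `step`, plus one anchored at the final frame so
  // the interpolation never extrapolates flat over a trailing drift
  std::vector<int> cgrid;
  for (int c = 0; c < L; c += step) cgrid.push_back(c);
  if (cgrid.back() != L - 1) cgrid.push_back(L - 1);
  for (int iter = 0; iter < max_iter; ++iter) {
    centres.clear();
    values.clear();
    for (int c : cgrid) {
      int lo = c - width / 2, hi = c + width / 2;
      if (lo < 0) lo = 0;
      if (hi > L) hi = L;
      buf.clear();
      for (int k = lo; k < hi; ++k)
        if (!masked[k]) buf.push_back(x[k]);
      if ((int)buf.size() < min_keep) {
        buf.clear();
        for (int k = lo; k < hi; ++k) buf.push_back(x[k]);
      }
      centres.push_back((double)c);
      values.push_back(quantile7(buf, p));
    }
    // linear interpolation of the centre values onto every frame
    const int nc = centres.size();
    int seg = 0;
    for (int k = 0; k < L; ++k) {
      if (k <= centres[0]) { f0[k] = values[0]; continue; }
      if (k >= centres[nc - 1]) { f0[k] = values[nc - 1]; continue; }
      while (centres[seg + 1] < k) ++seg;
      double w = (k - centres[seg]) / (centres[seg + 1] - centres[seg]);
      f0[k] = values[seg] + w * (values[seg + 1] - values[seg]);
    }
    // robust scale of the inactive residuals (strided subsample)
    resid_s.clear();
    int n_inact = 0;
    for (int k = 0; k < L; ++k) n_inact += !masked[k];
    int stride = std::max(1, n_inact / 6000);
    int seen = 0;
    for (int k = 0; k < L; ++k) {
      if (masked[k]) continue;
      if (seen++ % stride == 0) resid_s.push_back(x[k] - f0[k]);
    }
    std::vector<double> tmp(resid_s);
    double centre = quantile7(tmp, 0.5);
    for (double &v : tmp) v = std::fabs(v - centre);
    double rsd = 1.4826 * quantile7(tmp, 0.5);
    if (!(rsd > 1e-12)) break;
    int changed = 0;
    for (int k = 0; k < L; ++k) {
      char m = (x[k] - f0[k]) > centre + 2 * rsd;
      changed += (m != masked[k]);
      masked[k] = m;
    }
    if (changed <= tol_frac * L) break;
  }
  return f0;
}

static inline double median_inplace(std::vector<double> &v) {
  const int n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return 0.5 * (lo + hi);
}

// Null distribution of the cohort-mean percent-responsive statistic.
// profiles: one integer matrix per mouse (n_valid_starts x n_active_neurons,
// 0/1), value [w, n] = neuron n meets the z/run criterion in the 2.5-s window
// starting at frame w. n_draws: included-trial count per mouse.
// Each iteration: bootstrap mice, per sampled mouse draw n_draws windows,
// per draw percent responsive over active neurons, median over draws,
// mean over mice.
// [[Rcpp::export]]
NumericVector cpp_null_percent_responsive(List profiles, IntegerVector n_draws,
                                          int n_iter) {
  const int M = profiles.size();
  std::vector<IntegerMatrix> mats(M);
  for (int m = 0; m < M; ++m) mats[m] = as<IntegerMatrix>(profiles[m]);
  NumericVector out(n_iter);
  std::vector<double> draws;
  for (int it = 0; it < n_iter; ++it) {
    double acc = 0.0;
    for (int mi = 0; mi < M; ++mi) {
      int m = runif_int(M); // bootstrap mice with replacement
      const IntegerMatrix &P = mats[m];
      const int W = P.nrow(), N = P.ncol(), D = n_draws[m];
      draws.assign(D, 0.0);
      for (int d = 0; d < D; ++d) {
        int w = runif_int(W);
        int hits = 0;
        for (int n = 0; n < N; ++n) hits += P(w, n);
        draws[d] = 100.0 * hits / N;
      }
      acc += median_inplace(draws);
    }
    out[it] = acc / M;
  }
  return out;
}

// average ranks (ties resolved by midranks) of v into r
static void avg_ranks(const std::vector<double> &v, std::vector<double> &r,
                      std::vector<std::pair<double, int> > &buf) {
  const int n = v.size();
  buf.resize(n);
  r.resize(n);
  for (int i = 0; i < n; ++i) buf[i] = std::make_pair(v[i], i);
  std::sort(buf.begin(), buf.end());
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && buf[j + 1].first == buf[i].first) ++j;
    double rank = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[buf[k].second] = rank;
    i = j + 1;
  }
}

// Pearson correlation between ranks of x and a binary indicator
// (== Spearman of x vs indicator, average ranks on both sides)
static double spearman_binary(const std::vector<double> &ranks,
                              const std::vector<int> &ones, int n) {
  const int n1 = ones.size();
  if (n1 == 0 || n1 == n) return NA_REAL;
  double mx = 0.0;
  for (int i = 0; i < n; ++i) mx += ranks[i];
  mx /= n;
  double sxx = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = ranks[i] - mx;
    sxx += d * d;
  }
  if (sxx <= 0) return NA_REAL;
  double s1 = 0.0;
  for (int k : ones) s1 += ranks[k];
  double my = (double)n1 / n;
  double sxy = s1 - n1 * mx; // sum (x - mx)(y - my) for binary y
  sxy -= 0; // remaining term cancels: sum over zeros of (x-mx)*(-my) folded in
  // full covariance: sum x_i y_i - n mx my = s1 - n1 * mx
  double syy = n1 * (1.0 - my);
  return sxy / std::sqrt(sxx * syy);
}

// Bootstrap/scramble null for the cohort mean change in Spearman tuning.
// z1, z7: per-mouse matrices (frames x neurons, z-scored dF, tracked active
// cells in matched column order across days). nt1/nt7: trial counts per
// mouse/day. grid_len: frames in the aligned analysis grid; indicator_pos:
// 0-based positions of the stimulus-period frames within the grid.
// Each iteration: bootstrap mice; per mouse/day draw nt uniform grid starts,
// average the snippets per neuron, Spearman vs the indicator, per-mouse mean
// of rho7 - rho1, mean over mice.
// [[Rcpp::export]]
NumericVector cpp_null_delta_rho(List z1, List z7, IntegerVector nt1,
                                 IntegerVector nt7, int grid_len,
                                 IntegerVector indicator_pos, int n_iter) {
  const int M = z1.size();
  std::vector<NumericMatrix> Z1(M), Z7(M);
  for (int m = 0; m < M; ++m) {
    Z1[m] = as<NumericMatrix>(z1[m]);
    Z7[m] = as<NumericMatrix>(z7[m]);
  }
  std::vector<int> ones(indicator_pos.begin(), indicator_pos.end());
  NumericVector out(n_iter);
  std::vector<double> avg(grid_len), ranks;
  std::vector<std::pair<double, int> > sortbuf;
  for (int it = 0; it < n_iter; ++it) {
    double acc_m = 0.0;
    int used_m = 0;
    for (int mi = 0; mi < M; ++mi) {
      int m = runif_int(M);
      const NumericMatrix &A = Z1[m], &B = Z7[m];
      const int N = A.ncol();
      if (N == 0) continue;
      // scrambled trial starts, shared across the mouse's neurons within a day
      const int W1 = A.nrow() - grid_len + 1, W7 = B.nrow() - grid_len + 1;
      std::vector<int> s1(nt1[m]), s7(nt7[m]);
      for (int t = 0; t < nt1[m]; ++t) s1[t] = runif_int(W1);
      for (int t = 0; t < nt7[m]; ++t) s7[t] = runif_int(W7);
      double acc_n = 0.0;
      int used_n = 0;
      for (int n = 0; n < N; ++n) {
        double rho[2];
        for (int d = 0; d < 2; ++d) {
          const NumericMatrix &Z = d == 0 ? A : B;
          const std::vector<int> &st = d == 0 ? s1 : s7;
          const double *col = &Z(0, n);
          std::fill(avg.begin(), avg.end(), 0.0);
          for (int s : st) {
            const double *p = col + s;
            for (int j = 0; j < grid_len; ++j) avg[j] += p[j];
          }
          const double inv = 1.0 / st.size();
          for (int j = 0; j < grid_len; ++j) avg[j] *= inv;
          avg_ranks(avg, ranks, sortbuf);
          rho[d] = spearman_binary(ranks, ones, grid_len);
        }
        if (R_IsNA(rho[0]) || R_IsNA(rho[1])) continue;
        acc_n += rho[1] - rho[0];
        ++used_n;
      }
      if (used_n > 0) {
        acc_m += acc_n / used_n;
        ++used_m;
      }
    }
    out[it] = used_m > 0 ? acc_m / used_m : NA_REAL;
  }
  return out;
}

// Spearman correlation of x against a binary indicator (exported so the R
// path and the null share one definition)
// [[Rcpp::export]]
double cpp_spearman_binary(NumericVector x, LogicalVector indicator) {
  const int n = x.size();
  if (indicator.size() != n) stop("length mismatch");
  std::vector<double> v(x.begin(), x.end()), ranks;
  std::vector<std::pair<double, int> > sortbuf;
  std::vector<int> ones;
  for (int i = 0; i < n; ++i)
    if (indicator[i]) ones.push_back(i);
  avg_ranks(v, ranks, sortbuf);
  return spearman_binary(ranks, ones, n);
}
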