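#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spike times are carried as integer sample indices; each spike is assigned to
// a lag-resolution bin of width `bw` samples (bw = delta_ms * fs / 1000).
// Pair lag = bin(target) - bin(reference), so the direct time-stamp sweep is
// exactly the shifted product of the two binned trains.
static std::vector<long> to_bins(const IntegerVector& s, double bw) {
  std::vector<long> b(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i)
    b[i] = (long)std::floor((double)s[i] / bw + 1e-12);
  return b;
}

// Pair counts per lag bin k in [-K, K] via a two-pointer sweep over the
// target train; never materializes binarized arrays.
static void sweep_counts(const std::vector<long>& bx, const std::vector<long>& by,
                         int K, std::vector<double>& counts) {
  std::fill(counts.begin(), counts.end(), 0.0);
  size_t lo = 0, hi = 0, ny = by.size();
  for (size_t i = 0; i < bx.size(); ++i) {
    long a = bx[i];
    while (lo < ny && by[lo] < a - K) ++lo;
    if (hi < lo) hi = lo;
    while (hi < ny && by[hi] <= a + K) ++hi;
    for (size_t j = lo; j < hi; ++j) counts[by[j] - a + K] += 1.0;
  }
}

// [[Rcpp::export]]
NumericVector ncch_counts_cpp(IntegerVector sx, IntegerVector sy, double bw, int K) {
  std::vector<long> bx = to_bins(sx, bw), by = to_bins(sy, bw);
  std::vector<double> counts(2 * K + 1);
  sweep_counts(bx, by, K, counts);
  return NumericVector(counts.begin(), counts.end());
}

// argmax of |F| over lags |k| <= kmax, visiting 0, +1, -1, +2, -2, ...
// Strict > keeps the earliest candidate: smallest |lag| wins, then positive lag.
static int pick_peak(const std::vector<double>& F, int K, int kmax) {
  int best = 0;
  double bv = -1.0;
  for (int m = 0; m <= kmax; ++m) {
    for (int s = 0; s < (m == 0 ? 1 : 2); ++s) {
      int k = (s == 0) ? m : -m;
      double v = std::fabs(F[k + K]);
      if (v > bv) { bv = v; best = k; }
    }
  }
  return best;
}

// All-pairs functional connectivity matrix from binned spike trains.
// estimator: 1 = FNCCH (mean-subtracted, signed extreme), 0 = plain NCCH max.
// [[Rcpp::export]]
List fcm_cpp(List samples, double bw, int K, int min_spikes,
             int estimator, bool refilter, double tail_fraction) {
  int n = samples.size();
  std::vector<std::vector<long> > bins(n);
  std::vector<double> nsp(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = samples[i];
    bins[i] = to_bins(s, bw);
    nsp[i] = (double)s.size();
  }
  NumericMatrix ent(n, n);
  IntegerMatrix lag(n, n);
  LogicalMatrix zerolag(n, n);
  int nb = 2 * K + 1;
  int kc = (int)std::floor(K * (1.0 - 2.0 * tail_fraction));
  std::vector<double> counts(nb), C(nb), F(nb);
  long skipped = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (nsp[i] == 0 || nsp[j] == 0) continue;
      if (nsp[i] < min_spikes && nsp[j] < min_spikes) { ++skipped; continue; }
      // reference i, target j; symmetry makes role swap equivalent
      sweep_counts(bins[i], bins[j], K, counts);
      double norm = std::sqrt(nsp[i] * nsp[j]);
      double tot = 0.0;
      for (int b = 0; b < nb; ++b) { C[b] = counts[b] / norm; tot += C[b]; }
      if (tot == 0.0) continue;
      double entity; int k;
      if (estimator == 1) {
        double mu = tot / nb;
        for (int b = 0; b < nb; ++b) F[b] = C[b] - mu;
        k = pick_peak(F, K, K);
        entity = F[k + K];
        if (refilter && entity < 0 && std::abs(k) > kc) {
          k = pick_peak(F, K, kc);
          entity = F[k + K];
        }
      } else {
        k = pick_peak(C, K, K);
        entity = C[k + K];
      }
      if (entity == 0.0) continue;
      if (k > 0)      { ent(i, j) = entity; lag(i, j) = k; }
      else if (k < 0) { ent(j, i) = entity; lag(j, i) = -k; }
      else            { ent(i, j) = entity; lag(i, j) = 0; zerolag(i, j) = true; }
    }
  }
  return List::create(_["entity"] = ent, _["lag_bins"] = lag,
                      _["zero_lag"] = zerolag, _["skipped_pairs"] = skipped);
}
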