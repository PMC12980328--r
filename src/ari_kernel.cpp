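#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Batched Adjusted Rand Index kernel.
//
// P holds one partition per column (0-based labels over the same samples);
// ks[j] is the number of clusters of column j. Each task t crosses columns
// task_x[t] and task_y[t]. The contingency buffer is sized once for the
// largest k and reused across every task in the batch, mirroring the
// buffer-reuse discipline of the batched execution architecture.
//
// All counts are small integers, exactly representable in double, so the
// floating-point result does not depend on summation order and is
// bit-identical to the pure-R reference backend.

// [[Rcpp::export]]
NumericVector cpp_ari_batch(const IntegerMatrix& P,
                            const IntegerVector& ks,
                            const IntegerVector& task_x,
                            const IntegerVector& task_y) {
  const int n = P.nrow();
  const int nt = task_x.size();
  int kmax = 1;
  for (int j = 0; j < ks.size(); ++j) kmax = std::max(kmax, ks[j]);

  std::vector<int> tab((size_t)kmax * kmax);
  std::vector<double> a(kmax), b(kmax);
  NumericVector out(nt);
  const double cn2 = (double)n * (n - 1) / 2.0;

  for (int t = 0; t < nt; ++t) {
    const int cx = task_x[t], cy = task_y[t];
    const int kx = ks[cx], ky = ks[cy];
    std::fill(tab.begin(), tab.begin() + (size_t)kx * ky, 0);
    const int* px = &P(0, cx);
    const int* py = &P(0, cy);
    for (int s = 0; s < n; ++s) tab[(size_t)px[s] * ky + py[s]]++;

    std::fill(a.begin(), a.begin() + kx, 0.0);
    std::fill(b.begin(), b.begin() + ky, 0.0);
    double sij = 0.0;
    for (int i = 0; i < kx; ++i) {
      for (int j = 0; j < ky; ++j) {
        const double c = tab[(size_t)i * ky + j];
        sij += c * (c - 1) / 2.0;
        a[i] += c;
        b[j] += c;
      }
    }
    double sa = 0.0, sb = 0.0;
    for (int i = 0; i < kx; ++i) sa += a[i] * (a[i] - 1) / 2.0;
    for (int j = 0; j < ky; ++j) sb += b[j] * (b[j] - 1) / 2.0;

    const double E = sa * sb / cn2;
    const double num = sij - E;
    const double den = 0.5 * (sa + sb) - E;
    out[t] = (num == 0.0 && den == 0.0) ? 1.0 : num / den;
  }
  return out;
}

// Deterministic per-pair max-reduction: for each contiguous segment of the
// task stream (one segment per feature pair), returns the maximum ARI and
// the first task index attaining it (lowest global index wins ties).

// [[Rcpp::export]]
List cpp_segment_max(const NumericVector& x,
                     const IntegerVector& start,
                     const IntegerVector& len) {
  const int np = start.size();
  NumericVector mx(np);
  IntegerVector arg(np);
  for (int p = 0; p < np; ++p) {
    const int s = start[p], l = len[p];
    double best = x[s];
    int besti = s;
    for (int t = s + 1; t < s + l; ++t) {
      if (x[t] > best) { best = x[t]; besti = t; }
    }
    mx[p] = best;
    arg[p] = besti;  // 0-based global task index
  }
  return List::create(Named("max") = mx, Named("argmax") = arg);
}
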