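#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Window starts (0-based): 0, step, 2*step, ... while the window fits;
// the final start is clamped to n - w so every point is covered.
static std::vector<int> window_starts(int n, int w, int step) {
  std::vector<int> starts;
  for (int s = 0; s + w <= n; s += step) starts.push_back(s);
  if (starts.empty() || starts.back() != n - w) starts.push_back(n - w);
  return starts;
}

// Indices of the top-k points of window [s, s+w) ranked by intensity
// descending, ties by lower index (lower m/z) first.
static void mark_top_k(const NumericVector& x, int s, int w, int k,
                       std::vector<int>& idx, std::vector<char>& out) {
  idx.resize(w);
  for (int i = 0; i < w; ++i) idx[i] = s + i;
  std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                    [&x](int a, int b) {
                      if (x[a] != x[b]) return x[a] > x[b];
                      return a < b;
                    });
  std::fill(out.begin(), out.end(), 0);
  for (int i = 0; i < k; ++i) out[idx[i] - s] = 1;
}

// [[Rcpp::export]]
NumericVector denoise_cpp(NumericVector x, int w, double keep_fraction,
                          int step, bool per_window) {
  int n = x.size();
  if (w > n) stop("window larger than grid");
  int k = (int)std::ceil(keep_fraction * w);
  if (k < 1) k = 1;
  if (k > w) k = w;
  std::vector<int> starts = window_starts(n, w, step);
  std::vector<int> idx;
  std::vector<char> marked(w);
  NumericVector out(n);
  if (per_window) {
    // last-writer: each window in start order overwrites its span
    for (int i = 0; i < n; ++i) out[i] = x[i];
    for (int s : starts) {
      mark_top_k(x, s, w, k, idx, marked);
      for (int i = 0; i < w; ++i) out[s + i] = marked[i] ? x[s + i] : 0.0;
    }
  } else {
    std::vector<char> keep(n, 0);
    for (int s : starts) {
      mark_top_k(x, s, w, k, idx, marked);
      for (int i = 0; i < w; ++i) if (marked[i]) keep[s + i] = 1;
    }
    for (int i = 0; i < n; ++i) out[i] = keep[i] ? x[i] : 0.0;
  }
  return out;
}
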