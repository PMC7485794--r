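#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// x log x with the 0 log 0 = 0 convention
static inline double xlx(double c) { return c > 0.0 ? c * std::log(c) : 0.0; }

// Best mutual information (nats) achievable for each column count 2..cmax
// when the y axis is equipartitioned into r bins and the x axis is cut by
// dynamic programming over positions along the x-sorted order.
//
// ylab: y bin label (0..r-1) of each point in x-sorted order.
// allowed[i] == true when a cut may be placed after position i+1 (i.e. the
// boundary does not split tied x values).
//
// Writes MI for k columns into mi[k] (k = 2..cmax); unreachable k keep -1.
static void dp_orientation(const std::vector<int>& ylab,
                           const std::vector<bool>& allowed,
                           int r, int cmax, std::vector<double>& mi) {
  const int n = static_cast<int>(ylab.size());

  // segment cost(j, i) = nb*log(nb) - sum_l c_l log c_l over points j+1..i,
  // i.e. nb * H(Y | segment); filled incrementally in O(n^2).
  std::vector<double> cost(static_cast<size_t>(n + 1) * (n + 1), 0.0);
  std::vector<int> cnt(r);
  for (int j = 0; j < n; ++j) {
    std::fill(cnt.begin(), cnt.end(), 0);
    double S = 0.0; // sum_l c_l log c_l
    for (int i = j + 1; i <= n; ++i) {
      int l = ylab[i - 1];
      S += xlx(cnt[l] + 1.0) - xlx(static_cast<double>(cnt[l]));
      cnt[l] += 1;
      int nb = i - j;
      cost[static_cast<size_t>(j) * (n + 1) + i] = xlx(nb) - S;
    }
  }

  // marginal entropy of the y binning (nats)
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int i = 0; i < n; ++i) cnt[ylab[i]] += 1;
  double Sy = 0.0;
  for (int l = 0; l < r; ++l) Sy += xlx(static_cast<double>(cnt[l]));
  const double Hy = (xlx(static_cast<double>(n)) - Sy) / n;

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(n + 1, INF), cur(n + 1, INF);
  // k = 1 segment
  for (int i = 1; i <= n; ++i) prev[i] = cost[i];

  for (int k = 2; k <= cmax; ++k) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int i = k; i <= n; ++i) {
      double best = INF;
      const double* crow = &cost[0];
      for (int j = k - 1; j < i; ++j) {
        if (!(j == 0 || allowed[j - 1])) continue;
        if (prev[j] == INF) continue;
        double v = prev[j] + crow[static_cast<size_t>(j) * (n + 1) + i];
        if (v < best) best = v;
      }
      cur[i] = best;
    }
    if (cur[n] < INF) mi[k] = Hy - cur[n] / n;
    std::swap(prev, cur);
  }
}

// Equal-frequency bin labels (0..r-1) for v, assigned along the sort order
// of v; returns labels aligned to the original order of v.
static std::vector<int> equifreq_labels(const std::vector<double>& v, int r) {
  const int n = static_cast<int>(v.size());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  std::vector<int> lab(n);
  for (int pos = 0; pos < n; ++pos) {
    int bin = static_cast<int>((static_cast<long long>(pos) * r) / n);
    if (bin >= r) bin = r - 1;
    lab[ord[pos]] = bin;
  }
  return lab;
}

// One search orientation: equipartition `ybin` into r bins (r = 2..B/2),
// DP-partition along `xaxis`; returns max over shapes of
// MI / log(min(r, c)) subject to r * c <= B.
static double mic_one_orientation(const std::vector<double>& xaxis,
                                  const std::vector<double>& ybin,
                                  int B) {
  const int n = static_cast<int>(xaxis.size());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return xaxis[a] < xaxis[b]; });
  std::vector<bool> allowed(n - 1);
  for (int i = 0; i + 1 < n; ++i) {
    allowed[i] = xaxis[ord[i]] != xaxis[ord[i + 1]];
  }

  double best = 0.0;
  for (int r = 2; r * 2 <= B; ++r) {
    int cmax = B / r;
    if (cmax < 2) break;
    std::vector<int> lab_orig = equifreq_labels(ybin, r);
    std::vector<int> ylab(n);
    for (int pos = 0; pos < n; ++pos) ylab[pos] = lab_orig[ord[pos]];

    std::vector<double> mi(cmax + 1, -1.0);
    dp_orientation(ylab, allowed, r, cmax, mi);
    for (int c = 2; c <= cmax; ++c) {
      if (mi[c] < 0) continue;
      double denom = std::log(static_cast<double>(std::min(r, c)));
      double val = mi[c] / denom;
      if (val > best) best = val;
    }
  }
  return best;
}

// [[Rcpp::export]]
double mic_cpp(NumericVector x, NumericVector y, int max_cells) {
  const int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (n < 4) stop("need at least 4 observations");
  if (max_cells < 4) stop("grid-cell bound must be at least 4");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  double a = mic_one_orientation(xv, yv, max_cells);
  double b = mic_one_orientation(yv, xv, max_cells);
  double out = std::max(a, b);
  return out > 1.0 ? 1.0 : out; // guard round-off
}
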