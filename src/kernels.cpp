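#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Forward-deletion refractory filter: keep a spike only if it follows the
// last kept spike by more than t_refr (the earlier spike wins).
// [[Rcpp::export]]
LogicalVector refractory_keep_cpp(NumericVector t, double t_refr) {
  int n = t.size();
  LogicalVector keep(n);
  double last = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    if (t[i] - last > t_refr) { keep[i] = true; last = t[i]; }
  }
  return keep;
}

// Victor-Purpura spike train distance by dynamic programming.
// Edit operations: insert/delete cost 1, shift cost q*|dt|.
// [[Rcpp::export]]
double vp_distance_cpp(NumericVector a, NumericVector b, double q) {
  int n = a.size(), m = b.size();
  if (n == 0) return (double)m;
  if (m == 0) return (double)n;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// One-sided decayed cross sum: sum over pairs x_i (<= or <) y_j of
// exp(-(y_j - x_i)/tau). Linear time, numerically stable (only decays).
static double one_sided_exp(const NumericVector& x, const NumericVector& y,
                            double tau, bool strict) {
  int n = x.size(), m = y.size();
  double S = 0.0, total = 0.0, ref = 0.0;
  int i = 0;
  bool started = false;
  for (int j = 0; j < m; ++j) {
    while (i < n && (strict ? x[i] < y[j] : x[i] <= y[j])) {
      if (started) S *= std::exp(-(x[i] - ref) / tau);
      S += 1.0;
      ref = x[i];
      started = true;
      ++i;
    }
    if (started) {
      S *= std::exp(-(y[j] - ref) / tau);
      ref = y[j];
      total += S;
    }
  }
  return total;
}

// Full double sum over pairs of exp(-|a_i - b_j|/tau).
// [[Rcpp::export]]
double exp_cross_sum_cpp(NumericVector a, NumericVector b, double tau) {
  return one_sided_exp(a, b, tau, false) + one_sided_exp(b, a, tau, true);
}

// Double sum over pairs of exp(-(a_i - b_j)^2 / (2 s^2)), windowed at 6 s.
// [[Rcpp::export]]
double gauss_cross_sum_cpp(NumericVector a, NumericVector b, double s) {
  int n = a.size(), m = b.size();
  double w = 6.0 * s, total = 0.0, inv = 1.0 / (2.0 * s * s);
  int lo = 0;
  for (int i = 0; i < n; ++i) {
    while (lo < m && b[lo] < a[i] - w) ++lo;
    for (int j = lo; j < m && b[j] <= a[i] + w; ++j) {
      double d = a[i] - b[j];
      total += std::exp(-d * d * inv);
    }
  }
  return total;
}

// Number of spike pairs with |a_i - b_j| <= tau.
// [[Rcpp::export]]
double count_within_cpp(NumericVector a, NumericVector b, double tau) {
  int n = a.size(), m = b.size();
  double total = 0.0;
  int lo = 0, hi = 0;
  for (int i = 0; i < n; ++i) {
    while (lo < m && b[lo] < a[i] - tau) ++lo;
    if (hi < lo) hi = lo;
    while (hi < m && b[hi] <= a[i] + tau) ++hi;
    total += hi - lo;
  }
  return total;
}

// Length of the union of [a_i - tau, a_i + tau] intersected with [0, T].
// [[Rcpp::export]]
double tiling_coverage_cpp(NumericVector a, double tau, double T) {
  int n = a.size();
  if (n == 0) return 0.0;
  double total = 0.0;
  double lo = std::max(0.0, a[0] - tau), hi = std::min(T, a[0] + tau);
  for (int i = 1; i < n; ++i) {
    double l = std::max(0.0, a[i] - tau), h = std::min(T, a[i] + tau);
    if (l <= hi) { if (h > hi) hi = h; }
    else { total += hi - lo; lo = l; hi = h; }
  }
  total += hi - lo;
  return total;
}

// For each spike of a, distance to the nearest spike of b.
// [[Rcpp::export]]
NumericVector nearest_dist_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  NumericVector out(n);
  if (m == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  int j = 0;
  for (int i = 0; i < n; ++i) {
    while (j < m - 1 && b[j + 1] <= a[i]) ++j;
    double d = std::fabs(a[i] - b[j]);
    if (j < m - 1) d = std::min(d, std::fabs(b[j + 1] - a[i]));
    out[i] = d;
  }
  return out;
}

// Directed event-synchronization counts with a fixed coincidence window:
// c_ab counts pairs with 0 < a_i - b_j <= tau (a follows b), ties at
// a_i == b_j contribute 0.5 to each direction. Returns (c_ab, c_ba).
// [[Rcpp::export]]
NumericVector qq_counts_cpp(NumericVector a, NumericVector b, double tau) {
  int n = a.size(), m = b.size();
  double cab = 0.0, cba = 0.0;
  int lo = 0, hi = 0;
  for (int i = 0; i < n; ++i) {
    while (lo < m && b[lo] < a[i] - tau) ++lo;
    if (hi < lo) hi = lo;
    while (hi < m && b[hi] <= a[i] + tau) ++hi;
    for (int j = lo; j < hi; ++j) {
      double d = a[i] - b[j];
      if (d == 0.0) { cab += 0.5; cba += 0.5; }
      else if (d > 0.0) cab += 1.0;
      else cba += 1.0;
    }
  }
  // restrict cba to pairs with 0 < b_j - a_i <= tau (already ensured by window)
  return NumericVector::create(cab, cba);
}

static inline double local_tau(const NumericVector& a, int i,
                               const NumericVector& b, int j) {
  double inf = std::numeric_limits<double>::infinity();
  double p1 = i > 0 ? a[i] - a[i - 1] : inf;
  double n1 = i < a.size() - 1 ? a[i + 1] - a[i] : inf;
  double p2 = j > 0 ? b[j] - b[j - 1] : inf;
  double n2 = j < b.size() - 1 ? b[j + 1] - b[j] : inf;
  double t = std::min(std::min(p1, n1), std::min(p2, n2));
  return 0.5 * t;
}

// Timescale-adaptive event-synchronization counts: the coincidence
// window for a spike pair is half the minimum of the four adjacent
// inter-spike intervals, so at most the immediately preceding spike of
// the other train can match. Returns (c_ab, c_ba) as above.
// [[Rcpp::export]]
NumericVector qq_adaptive_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  double cab = 0.0, cba = 0.0;
  // a following b
  int j = 0;
  for (int i = 0; i < n; ++i) {
    while (j < m - 1 && b[j + 1] <= a[i]) ++j;
    if (m > 0 && b[j] <= a[i]) {
      double d = a[i] - b[j];
      double tau = local_tau(a, i, b, j);
      if (d == 0.0) { cab += 0.5; cba += 0.5; }
      else if (d <= tau) cab += 1.0;
    }
  }
  // b following a (strictly, ties already counted)
  int i2 = 0;
  for (int jj = 0; jj < m; ++jj) {
    while (i2 < n - 1 && a[i2 + 1] <= b[jj]) ++i2;
    if (n > 0 && a[i2] < b[jj]) {
      double d = b[jj] - a[i2];
      double tau = local_tau(b, jj, a, i2);
      if (d <= tau) cba += 1.0;
    }
  }
  return NumericVector::create(cab, cba);
}

// Pairwise SPIKE-synchronization: number of coincident spikes of a and
// of b under the adaptive window |dt| < tau_ij. Returns (hits_a, hits_b).
// [[Rcpp::export]]
NumericVector spike_sync_pair_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  double ha = 0.0, hb = 0.0;
  int j = 0;
  for (int i = 0; i < n; ++i) {
    while (j < m - 1 && b[j + 1] <= a[i]) ++j;
    double d = std::fabs(a[i] - b[j]);
    int jn = j;
    if (j < m - 1 && std::fabs(b[j + 1] - a[i]) < d) {
      d = std::fabs(b[j + 1] - a[i]); jn = j + 1;
    }
    if (m > 0 && d < local_tau(a, i, b, jn)) ha += 1.0;
  }
  int i2 = 0;
  for (int jj = 0; jj < m; ++jj) {
    while (i2 < n - 1 && a[i2 + 1] <= b[jj]) ++i2;
    double d = std::fabs(b[jj] - a[i2]);
    int in = i2;
    if (i2 < n - 1 && std::fabs(a[i2 + 1] - b[jj]) < d) {
      d = std::fabs(a[i2 + 1] - b[jj]); in = i2 + 1;
    }
    if (n > 0 && d < local_tau(b, jj, a, in)) hb += 1.0;
  }
  return NumericVector::create(ha, hb);
}

// Lempel-Ziv 76 phrase count of an integer symbol sequence: the number
// of phrases in the self-referential LZ parsing, where each phrase is
// the shortest prefix of the remainder that has not occurred starting
// at an earlier position (the trailing partial phrase counts as one).
// Linear time via a suffix automaton with minimal-end-position
// propagation.
struct SamState {
  int next0, next1, link, len, minend;
};

// [[Rcpp::export]]
int lz76_complexity_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  std::vector<SamState> st;
  st.reserve(2 * n + 2);
  st.push_back({-1, -1, -1, 0, INT_MAX});
  int last = 0;
  auto getnext = [&](int v, int c) -> int& {
    return c == 0 ? st[v].next0 : st[v].next1;
  };
  for (int i = 0; i < n; ++i) {
    int c = s[i] ? 1 : 0;
    int cur = (int)st.size();
    st.push_back({-1, -1, -1, st[last].len + 1, i});
    int p = last;
    while (p != -1 && getnext(p, c) == -1) {
      getnext(p, c) = cur;
      p = st[p].link;
    }
    if (p == -1) {
      st[cur].link = 0;
    } else {
      int q = getnext(p, c);
      if (st[p].len + 1 == st[q].len) {
        st[cur].link = q;
      } else {
        int clone = (int)st.size();
        st.push_back(st[q]);
        st[clone].len = st[p].len + 1;
        while (p != -1 && getnext(p, c) == q) {
          getnext(p, c) = clone;
          p = st[p].link;
        }
        st[q].link = clone;
        st[cur].link = clone;
      }
    }
    last = cur;
  }
  // propagate minimal end positions up the suffix links (len-descending,
  // via counting sort on len)
  int m = (int)st.size();
  std::vector<int> cnt(n + 2, 0);
  for (int i = 0; i < m; ++i) ++cnt[st[i].len];
  for (int l = 1; l <= n + 1; ++l) cnt[l] += cnt[l - 1];
  std::vector<int> order(m);
  for (int i = m - 1; i >= 0; --i) order[--cnt[st[i].len]] = i;
  std::reverse(order.begin(), order.end());
  for (int idx : order) {
    int l = st[idx].link;
    if (l >= 0 && st[idx].minend < st[l].minend)
      st[l].minend = st[idx].minend;
  }
  // LZ factorization with self-overlap: extend the match while the
  // matched substring has an occurrence starting before the phrase
  int c_count = 0, p = 0;
  while (p < n) {
    int k = 0, cur = 0;
    while (p + k < n) {
      int ch = s[p + k] ? 1 : 0;
      int nxt = getnext(cur, ch);
      if (nxt == -1) break;
      // first occurrence of the (k+1)-length match starts at
      // minend - k; require it to start before p
      if (st[nxt].minend - k < p) { cur = nxt; ++k; }
      else break;
    }
    ++c_count;
    p += k + 1;
  }
  return c_count;
}

// Exact integral over [0, T] of |d(t, a) - d(t, b)| where d(t, x) is the
// distance from t to the nearest spike of x (modulus metric). Both
// distance functions are piecewise linear with slopes +-1; breakpoints
// are spikes and midpoints between consecutive spikes.
// [[Rcpp::export]]
double modulus_metric_cpp(NumericVector a, NumericVector b, double T) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return NA_REAL;
  std::vector<double> bp;
  bp.reserve(2 * (n + m) + 2);
  bp.push_back(0.0); bp.push_back(T);
  for (int i = 0; i < n; ++i) {
    if (a[i] > 0 && a[i] < T) bp.push_back(a[i]);
    if (i > 0) { double mid = 0.5 * (a[i - 1] + a[i]);
      if (mid > 0 && mid < T) bp.push_back(mid); }
  }
  for (int j = 0; j < m; ++j) {
    if (b[j] > 0 && b[j] < T) bp.push_back(b[j]);
    if (j > 0) { double mid = 0.5 * (b[j - 1] + b[j]);
      if (mid > 0 && mid < T) bp.push_back(mid); }
  }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
  int ia = 0, ib = 0;
  double total = 0.0;
  auto dist = [](const NumericVector& x, int& idx, double t) {
    int mm = x.size();
    while (idx < mm - 1 && x[idx + 1] <= t) ++idx;
    double d = std::fabs(t - x[idx]);
    if (idx < mm - 1) d = std::min(d, std::fabs(x[idx + 1] - t));
    return d;
  };
  for (size_t k = 0; k + 1 < bp.size(); ++k) {
    double t0 = bp[k], t1 = bp[k + 1], h = t1 - t0;
    if (h <= 0) continue;
    int ja = ia, jb = ib;
    double u0 = dist(a, ja, t0) - dist(b, jb, t0);
    ia = ja; ib = jb;
    double u1 = dist(a, ja, t1 - 1e-15) - dist(b, jb, t1 - 1e-15);
    if (u0 * u1 >= 0) total += h * 0.5 * (std::fabs(u0) + std::fabs(u1));
    else total += h * 0.5 * (u0 * u0 + u1 * u1) / std::fabs(u0 - u1);
  }
  return total;
}

// mean over [0, T] of the time-resolved dissimilarity profile between the
// nearest-spike structures of two trains (SPIKE-distance). Auxiliary
// spikes at 0 and T provide the edge correction.
// [[Rcpp::export]]
double spike_distance_cpp(NumericVector a, NumericVector b, double T) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return NA_REAL;
  std::vector<double> x(n + 2), y(m + 2);
  x[0] = 0.0; for (int i = 0; i < n; ++i) x[i + 1] = a[i]; x[n + 1] = T;
  y[0] = 0.0; for (int j = 0; j < m; ++j) y[j + 1] = b[j]; y[m + 1] = T;
  // merged event times
  std::vector<double> ev;
  ev.reserve(x.size() + y.size());
  std::merge(x.begin(), x.end(), y.begin(), y.end(), std::back_inserter(ev));
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
  auto nearest = [](const std::vector<double>& v, double t) {
    auto it = std::lower_bound(v.begin(), v.end(), t);
    double d = std::numeric_limits<double>::infinity();
    if (it != v.end()) d = std::min(d, std::fabs(*it - t));
    if (it != v.begin()) d = std::min(d, std::fabs(*(it - 1) - t));
    return d;
  };
  double total = 0.0;
  size_t ix = 0, iy = 0;
  for (size_t k = 0; k + 1 < ev.size(); ++k) {
    double t0 = ev[k], t1 = ev[k + 1], h = t1 - t0;
    if (h <= 0) continue;
    while (ix + 1 < x.size() - 1 && x[ix + 1] <= t0) ++ix;
    while (iy + 1 < y.size() - 1 && y[iy + 1] <= t0) ++iy;
    double xp = x[ix], xf = x[ix + 1];
    double yp = y[iy], yf = y[iy + 1];
    double xisi = xf - xp, yisi = yf - yp;
    double dxp = nearest(y, xp), dxf = nearest(y, xf);
    double dyp = nearest(x, yp), dyf = nearest(x, yf);
    double denom = (xisi + yisi) * (xisi + yisi) / 2.0;
    auto Sat = [&](double t) {
      double s1 = (dxp * (xf - t) + dxf * (t - xp)) / xisi;
      double s2 = (dyp * (yf - t) + dyf * (t - yp)) / yisi;
      return (s1 * yisi + s2 * xisi) / denom;
    };
    total += h * 0.5 * (Sat(t0) + Sat(t1));
  }
  return total / T;
}

// Time-averaged absolute ISI-ratio profile (ISI-distance), with
// auxiliary spikes at 0 and T.
// [[Rcpp::export]]
double isi_distance_cpp(NumericVector a, NumericVector b, double T) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return NA_REAL;
  std::vector<double> x(n + 2), y(m + 2);
  x[0] = 0.0; for (int i = 0; i < n; ++i) x[i + 1] = a[i]; x[n + 1] = T;
  y[0] = 0.0; for (int j = 0; j < m; ++j) y[j + 1] = b[j]; y[m + 1] = T;
  std::vector<double> ev;
  ev.reserve(x.size() + y.size());
  std::merge(x.begin(), x.end(), y.begin(), y.end(), std::back_inserter(ev));
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
  double total = 0.0;
  size_t ix = 0, iy = 0;
  for (size_t k = 0; k + 1 < ev.size(); ++k) {
    double t0 = ev[k], h = ev[k + 1] - t0;
    if (h <= 0) continue;
    while (ix + 1 < x.size() - 1 && x[ix + 1] <= t0) ++ix;
    while (iy + 1 < y.size() - 1 && y[iy + 1] <= t0) ++iy;
    double xisi = x[ix + 1] - x[ix], yisi = y[iy + 1] - y[iy];
    double I = std::fabs(xisi - yisi) / std::max(xisi, yisi);
    total += h * I;
  }
  return total / T;
}
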