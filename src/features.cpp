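#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Time-domain / nonlinear feature kernels. Each operates on one signal
// (a column of the epoch matrix); matrix drivers loop over columns so the
// 9 channel x 4 band x n epoch extraction stays cheap.

static double pop_mean(const double* x, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i];
  return s / n;
}

// population variance (divisor n)
static double pop_var(const double* x, int n) {
  double mu = pop_mean(x, n), s = 0.0;
  for (int i = 0; i < n; ++i) { double d = x[i] - mu; s += d * d; }
  return s / n;
}

// Hjorth activity/mobility/complexity; constant signal -> (0,0,0)
static void hjorth_core(const double* x, int n, double* out) {
  double v0 = pop_var(x, n);
  if (v0 <= 0.0 || n < 3) { out[0] = v0 > 0 ? v0 : 0.0; out[1] = 0.0; out[2] = 0.0; return; }
  std::vector<double> d1(n - 1), d2(n - 2);
  for (int i = 0; i < n - 1; ++i) d1[i] = x[i + 1] - x[i];
  for (int i = 0; i < n - 2; ++i) d2[i] = d1[i + 1] - d1[i];
  double v1 = pop_var(d1.data(), n - 1);
  double v2 = pop_var(d2.data(), n - 2);
  double mob = std::sqrt(v1 / v0);
  out[0] = v0;
  out[1] = mob;
  if (v1 <= 0.0 || mob <= 0.0) { out[2] = 0.0; return; }
  out[2] = std::sqrt(v2 / v1) / mob;
}

// Shannon entropy (nats) of ordinal patterns; ties broken by index order.
static double perm_entropy_core(const double* x, int n, int order, int delay) {
  int nwin = n - (order - 1) * delay;
  if (nwin < 1) return NA_REAL;
  int space = 1;
  for (int i = 0; i < order; ++i) space *= order;
  std::vector<double> counts(space, 0.0);
  std::vector<int> idx(order);
  for (int t = 0; t < nwin; ++t) {
    for (int i = 0; i < order; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      double xa = x[t + a * delay], xb = x[t + b * delay];
      if (xa == xb) return a < b;
      return xa < xb;
    });
    int code = 0;
    for (int i = 0; i < order; ++i) code = code * order + idx[i];
    counts[code] += 1.0;
  }
  double H = 0.0;
  for (double c : counts)
    if (c > 0) { double p = c / nwin; H -= p * std::log(p); }
  return H;
}

static double ls_slope(const std::vector<double>& xs, const std::vector<double>& ys) {
  int m = (int)xs.size();
  double mx = 0, my = 0;
  for (int i = 0; i < m; ++i) { mx += xs[i]; my += ys[i]; }
  mx /= m; my /= m;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < m; ++i) { sxy += (xs[i] - mx) * (ys[i] - my); sxx += (xs[i] - mx) * (xs[i] - mx); }
  if (sxx <= 0) return NA_REAL;
  return sxy / sxx;
}

// Higuchi: slope of log mean curve length vs log(1/k), k = 1..kmax.
// Returns the raw (unclamped) slope; NA for degenerate (flat) signals.
static double higuchi_core(const double* x, int n, int kmax) {
  std::vector<double> lx, ly;
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    int mcount = 0;
    for (int m = 0; m < k; ++m) {
      int nm = (n - 1 - m) / k;
      if (nm < 1) continue;
      double L = 0.0;
      for (int i = 1; i <= nm; ++i) L += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      L *= (double)(n - 1) / ((double)nm * (double)k * (double)k);
      Lk += L;
      ++mcount;
    }
    if (mcount == 0) continue;
    Lk /= mcount;
    if (Lk <= 0.0) return NA_REAL;
    lx.push_back(std::log(1.0 / (double)k));
    ly.push_back(std::log(Lk));
  }
  if (lx.size() < 2) return NA_REAL;
  return ls_slope(lx, ly);
}

// Rescaled-range Hurst: slope of log E[R/S] vs log window size over a
// dyadic ladder. Raw slope; NA when degenerate.
static double hurst_core(const double* x, int n) {
  int wmin = (n >= 64) ? 16 : 8;
  std::vector<double> lw, lrs;
  for (int w = wmin; w <= n / 2; w *= 2) {
    int nb = n / w;
    double acc = 0.0;
    int cnt = 0;
    for (int b = 0; b < nb; ++b) {
      const double* seg = x + b * w;
      double mu = pop_mean(seg, w);
      double s2 = 0.0;
      for (int i = 0; i < w; ++i) { double d = seg[i] - mu; s2 += d * d; }
      s2 /= w;
      if (s2 <= 0.0) continue;
      double cum = 0.0, mx = -1e308, mn = 1e308;
      for (int i = 0; i < w; ++i) {
        cum += seg[i] - mu;
        if (cum > mx) mx = cum;
        if (cum < mn) mn = cum;
      }
      double R = mx - mn;
      acc += R / std::sqrt(s2);
      ++cnt;
    }
    if (cnt == 0) continue;
    lw.push_back(std::log((double)w));
    lrs.push_back(std::log(acc / cnt));
  }
  if (lw.size() < 2) return NA_REAL;
  return ls_slope(lw, lrs);
}

// Fisher-Pearson g1 and excess kurtosis g2 (population moments).
static void moments_core(const double* x, int n, double* out) {
  double mu = pop_mean(x, n);
  double m2 = 0, m3 = 0, m4 = 0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - mu;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
  }
  m2 /= n; m3 /= n; m4 /= n;
  if (m2 <= 0.0) { out[0] = 0.0; out[1] = 0.0; return; }
  out[0] = m3 / std::pow(m2, 1.5);
  out[1] = m4 / (m2 * m2) - 3.0;
}

// [[Rcpp::export]]
double cpp_perm_entropy(NumericVector x, int order, int delay) {
  return perm_entropy_core(REAL(x), x.size(), order, delay);
}

// [[Rcpp::export]]
double cpp_higuchi_raw(NumericVector x, int kmax) {
  return higuchi_core(REAL(x), x.size(), kmax);
}

// [[Rcpp::export]]
double cpp_hurst_raw(NumericVector x) {
  return hurst_core(REAL(x), x.size());
}

// [[Rcpp::export]]
NumericVector cpp_hjorth(NumericVector x) {
  NumericVector out(3);
  hjorth_core(REAL(x), x.size(), REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_moments(NumericVector x) {
  NumericVector out(2);
  moments_core(REAL(x), x.size(), REAL(out));
  return out;
}

// All eight time-domain/nonlinear features for every column of X
// (rows: activity, mobility, complexity, perm_ent, higuchi_raw,
//  hurst_raw, skewness, kurtosis).
// [[Rcpp::export]]
NumericMatrix cpp_feature_matrix(NumericMatrix X, int kmax, int pe_order, int pe_delay) {
  int n = X.nrow(), m = X.ncol();
  NumericMatrix out(8, m);
  for (int j = 0; j < m; ++j) {
    const double* x = &X(0, j);
    double hj[3], mo[2];
    hjorth_core(x, n, hj);
    moments_core(x, n, mo);
    out(0, j) = hj[0];
    out(1, j) = hj[1];
    out(2, j) = hj[2];
    out(3, j) = perm_entropy_core(x, n, pe_order, pe_delay);
    out(4, j) = higuchi_core(x, n, kmax);
    out(5, j) = hurst_core(x, n);
    out(6, j) = mo[0];
    out(7, j) = mo[1];
  }
  return out;
}

// k-nearest-neighbour class prediction, euclidean (metric=0) or
// manhattan (metric=1); majority vote, distance-ordered tie-break.
// [[Rcpp::export]]
IntegerVector cpp_knn_predict(NumericMatrix train, NumericMatrix test,
                              IntegerVector cl, int k, int metric, int nclass) {
  int ntr = train.nrow(), nte = test.nrow(), d = train.ncol();
  IntegerVector pred(nte);
  std::vector<std::pair<double, int>> dist(ntr);
  for (int i = 0; i < nte; ++i) {
    for (int j = 0; j < ntr; ++j) {
      double acc = 0.0;
      if (metric == 0) {
        for (int c = 0; c < d; ++c) { double df = test(i, c) - train(j, c); acc += df * df; }
      } else {
        for (int c = 0; c < d; ++c) acc += std::fabs(test(i, c) - train(j, c));
      }
      dist[j] = std::make_pair(acc, j);
    }
    int kk = std::min(k, ntr);
    std::partial_sort(dist.begin(), dist.begin() + kk, dist.end());
    std::vector<int> votes(nclass, 0);
    for (int j = 0; j < kk; ++j) votes[cl[dist[j].second]] += 1;
    int best = 0;
    for (int c = 1; c < nclass; ++c) if (votes[c] > votes[best]) best = c;
    // tie: fall back to the single nearest neighbour's class
    int maxv = votes[best], nmax = 0;
    for (int c = 0; c < nclass; ++c) if (votes[c] == maxv) ++nmax;
    if (nmax > 1) best = cl[dist[0].second];
    pred[i] = best;
  }
  return pred;
}
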