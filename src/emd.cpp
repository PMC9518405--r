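#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (xs, ys), evaluated at 0..n-1.
// xs strictly increasing; at least 2 knots (2 knots -> linear).
static std::vector<double> spline_eval(const std::vector<double>& xs,
                                       const std::vector<double>& ys,
                                       int n) {
  int k = xs.size();
  std::vector<double> out(n);
  if (k == 2) {
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int i = 0; i < n; ++i) out[i] = ys[0] + slope * (i - xs[0]);
    return out;
  }
  // second derivatives via tridiagonal solve (natural boundary)
  std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), m2(k);
  for (int i = 0; i < k - 1; ++i) h[i] = xs[i + 1] - xs[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[k - 1] = 1.0; z[k - 1] = 0.0; m2[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) m2[i] = z[i] - mu[i] * m2[i + 1];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double xv = (double)i;
    while (seg < k - 2 && xs[seg + 1] < xv) ++seg;
    double dx = xs[seg + 1] - xs[seg];
    double a = (xs[seg + 1] - xv) / dx;
    double b = (xv - xs[seg]) / dx;
    out[i] = a * ys[seg] + b * ys[seg + 1] +
      ((a * a * a - a) * m2[seg] + (b * b * b - b) * m2[seg + 1]) *
        (dx * dx) / 6.0;
  }
  return out;
}

// strict local maxima (value > left, >= right) and minima
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  int n = x.size();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) imax.push_back(i);
    else if (x[i] < x[i - 1] && x[i] <= x[i + 1]) imin.push_back(i);
  }
}

// envelope through extrema with mirrored boundary extrema
static std::vector<double> envelope(const std::vector<double>& x,
                                    const std::vector<int>& idx, int n) {
  int k = idx.size();
  std::vector<double> xs, ys;
  xs.reserve(k + 4); ys.reserve(k + 4);
  // mirror up to two leading extrema across t = 0
  int nmir = std::min(2, k);
  for (int i = nmir - 1; i >= 0; --i) {
    double t = -(double)idx[i];
    if (t < -(double)(n - 1)) continue;
    xs.push_back(t); ys.push_back(x[idx[i]]);
  }
  for (int i = 0; i < k; ++i) { xs.push_back(idx[i]); ys.push_back(x[idx[i]]); }
  for (int i = nmir - 1; i >= 0; --i) { // ascending mirrored abscissae
    double t = 2.0 * (n - 1) - idx[k - 1 - i];
    xs.push_back(t); ys.push_back(x[idx[k - 1 - i]]);
  }
  // drop duplicated abscissae (possible when an extremum sits at a boundary)
  std::vector<double> xs2, ys2;
  for (size_t i = 0; i < xs.size(); ++i) {
    if (xs2.empty() || xs[i] > xs2.back() + 1e-9) {
      xs2.push_back(xs[i]); ys2.push_back(ys[i]);
    }
  }
  return spline_eval(xs2, ys2, n);
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_siftings = 10, double tol = 0.2,
             int max_imfs = 16) {
  int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> imax, imin;

  for (int it = 0; it < max_imfs; ++it) {
    find_extrema(r, imax, imin);
    if ((int)imax.size() < 2 || (int)imin.size() < 2) break; // residue
    std::vector<double> h = r;
    for (int s = 0; s < max_siftings; ++s) {
      find_extrema(h, imax, imin);
      if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
      std::vector<double> up = envelope(h, imax, n);
      std::vector<double> lo = envelope(h, imin, n);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (up[i] + lo[i]);
        num += m * m;
        den += h[i] * h[i];
        h[i] -= m;
      }
      if (den > 0.0 && num / den < tol) break; // SD stopping criterion
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }

  NumericMatrix M(n, (int)imfs.size());
  for (size_t j = 0; j < imfs.size(); ++j)
    for (int i = 0; i < n; ++i) M(i, j) = imfs[j][i];
  return List::create(_["imfs"] = M,
                      _["residue"] = NumericVector(r.begin(), r.end()));
}

// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector y, int m, double r_abs) {
  int n = y.size();
  int nt = n - m; // number of templates (m-length and m+1-length aligned)
  double Bm = 0.0, Bm1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int t = 0; t < m; ++t) {
        double a = std::fabs(y[i + t] - y[j + t]);
        if (a > d) d = a;
      }
      if (d <= r_abs) {
        Bm += 1.0;
        if (std::fabs(y[i + m] - y[j + m]) <= r_abs) Bm1 += 1.0;
      }
    }
  }
  return NumericVector::create(Bm, Bm1);
}
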