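#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform (squared-distance lower envelope of
// parabolas, Felzenszwalb & Huttenlocher 2004), generalised to a physical
// sample spacing per axis. Sites carry squared distance 0; everything else
// starts at BIG. BIG is far above any squared distance reachable on a real
// image, so "no site on this line yet" propagates harmlessly between passes.
static const double BIG = 1e30;

// 1D pass over f (squared distances at positions i*s), result written to d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double r;
    for (;;) {
      double xv = v[k] * s;
      r = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (r <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = r;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Distance (um) from every pixel to the nearest site pixel.
// site: logical matrix; drow/dcol: spacing along rows / columns.
// [[Rcpp::export]]
NumericMatrix cpp_edt2d(const LogicalMatrix& site, double drow, double dcol) {
  int nr = site.nrow(), nc = site.ncol();
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = site(i, j) ? 0.0 : BIG;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass along columns (row index varies, spacing drow)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    dt1d(f, d, nr, drow);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  // pass along rows (column index varies, spacing dcol)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, d, nc, dcol);
    for (int j = 0; j < nc; ++j) g(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = (g(i, j) >= BIG) ? R_PosInf : std::sqrt(g(i, j));
  return g;
}

// 3D version; dim = (n1, n2, n3) with array stored column-major like an R
// array, spacing = physical step along each of the three dims.
// [[Rcpp::export]]
NumericVector cpp_edt3d(const LogicalVector& site, const IntegerVector& dim,
                        const NumericVector& spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = site[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax);

  // along dim 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = g[base + i];
      dt1d(f, d, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) g[base + i] = d[i];
    }
  // along dim 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = g[base + (R_xlen_t)j * n1];
      dt1d(f, d, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) g[base + (R_xlen_t)j * n1] = d[j];
    }
  // along dim 3
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = g[base + (R_xlen_t)k * plane];
      dt1d(f, d, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) g[base + (R_xlen_t)k * plane] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labelling of a 3D logical array (column-major).
// Returns integer labels, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& mask, const IntegerVector& dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  R_xlen_t plane = (R_xlen_t)n1 * n2;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / plane);
      int rem = (int)(p % plane);
      int j = rem / n1;
      int i = rem % n1;
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t pp = (R_xlen_t)kk * plane + (R_xlen_t)jj * n1 + ii;
        if (mask[pp] && lab[pp] == 0) {
          lab[pp] = next;
          stack.push_back(pp);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
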