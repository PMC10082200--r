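// Morphology primitives: exact Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope algorithm, per-axis spacing) and 2D connected
// component labelling.  Used for disk dilation, largest-component retention,
// hole filling and surface-distance metrics.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Large finite stand-in for +Inf: keeps the lower-envelope arithmetic finite.
// Real squared distances never exceed ~(1e4)^2 * spacing^2 here.
static const double DT_BIG = 1e30;

// 1D squared distance transform on samples at positions i*s, i = 0..n-1.
static void dt1d(const double *f, double *d, int n, double s,
                 std::vector<int> &v, std::vector<double> &z) {
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG; z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double inter;
    for (;;) {
      double xv = v[k] * s;
      inter = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (inter <= z[k] && k > 0) --k; else break;
    }
    if (inter <= z[k]) { // k == 0: replace
      v[0] = q; z[0] = -DT_BIG; z[1] = DT_BIG;
    } else {
      ++k;
      v[k] = q; z[k] = inter; z[k + 1] = DT_BIG;
    }
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// Squared EDT of a logical array (rank 1..3, column-major dims): distance from
// every cell to the nearest TRUE cell, axis spacings in `spacing` (same order
// as dim).  Cells unreachable (empty mask) come back >= 1e29.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nd = dim.size();
  if (nd < 1 || nd > 3) stop("edt: rank must be 1..3");
  if (spacing.size() != nd) stop("edt: spacing length mismatch");
  R_xlen_t total = 1;
  for (int i = 0; i < nd; ++i) total *= dim[i];
  if (mask.size() != total) stop("edt: mask/dim mismatch");
  std::vector<double> f(total);
  for (R_xlen_t i = 0; i < total; ++i) f[i] = mask[i] ? 0.0 : DT_BIG;

  int d0 = dim[0], d1 = nd > 1 ? dim[1] : 1, d2 = nd > 2 ? dim[2] : 1;
  int dmax = std::max(d0, std::max(d1, d2));
  std::vector<int> v; std::vector<double> z;
  std::vector<double> line(dmax), out(dmax);

  for (int k = 0; k < d2; ++k)             // axis 0 (fastest varying)
    for (int j = 0; j < d1; ++j) {
      double *p = &f[(R_xlen_t)k * d0 * d1 + (R_xlen_t)j * d0];
      dt1d(p, out.data(), d0, spacing[0], v, z);
      std::copy(out.begin(), out.begin() + d0, p);
    }
  if (nd > 1)                              // axis 1
    for (int k = 0; k < d2; ++k)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t base = (R_xlen_t)k * d0 * d1 + i;
        for (int j = 0; j < d1; ++j) line[j] = f[base + (R_xlen_t)j * d0];
        dt1d(line.data(), out.data(), d1, spacing[1], v, z);
        for (int j = 0; j < d1; ++j) f[base + (R_xlen_t)j * d0] = out[j];
      }
  if (nd > 2)                              // axis 2
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t base = (R_xlen_t)j * d0 + i;
        for (int k = 0; k < d2; ++k) line[k] = f[base + (R_xlen_t)k * d0 * d1];
        dt1d(line.data(), out.data(), d2, spacing[2], v, z);
        for (int k = 0; k < d2; ++k) f[base + (R_xlen_t)k * d0 * d1] = out[k];
      }

  NumericVector res(total);
  std::copy(f.begin(), f.end(), res.begin());
  res.attr("dim") = dim;
  return res;
}

// 2D connected components, connectivity 4 or 8.  0 = background, labels 1..n
// in column-major discovery order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int>> stack;
  int cur = 0;
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++cur;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = cur;
      while (!stack.empty()) {
        std::pair<int, int> rc = stack.back(); stack.pop_back();
        for (int t = 0; t < nnb; ++t) {
          int rr = rc.first + dr8[t], cc = rc.second + dc8[t];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = cur;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}
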