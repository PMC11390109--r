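#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Terrain ruggedness: mean absolute elevation difference between a cell and
// its (up to 8) valid neighbours. Edge cells use the neighbours they have;
// NA cells propagate and are skipped as neighbours.
// [[Rcpp::export]]
NumericMatrix tri_cpp(NumericMatrix dem) {
  int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double z = dem(r, c);
      if (NumericMatrix::is_na(z)) { out(r, c) = NA_REAL; continue; }
      double s = 0.0; int n = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double zn = dem(rr, cc);
          if (NumericMatrix::is_na(zn)) continue;
          s += std::fabs(zn - z); ++n;
        }
      }
      out(r, c) = (n > 0) ? s / n : NA_REAL;
    }
  }
  return out;
}

// Topographic position: focal elevation minus the mean elevation over cells
// whose centre-to-centre distance d satisfies inner < d <= outer (metres).
// Cells with an empty annulus (or all-NA annulus) get NA.
// [[Rcpp::export]]
NumericMatrix tpi_cpp(NumericMatrix dem, double cell, double inner, double outer) {
  int nr = dem.nrow(), nc = dem.ncol();
  int w = (int)std::floor(outer / cell) + 1;
  std::vector<int> odr, odc;
  for (int dr = -w; dr <= w; ++dr) {
    for (int dc = -w; dc <= w; ++dc) {
      double d = cell * std::sqrt((double)(dr * dr + dc * dc));
      if (d > inner && d <= outer) { odr.push_back(dr); odc.push_back(dc); }
    }
  }
  int K = (int)odr.size();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double z = dem(r, c);
      if (NumericMatrix::is_na(z)) { out(r, c) = NA_REAL; continue; }
      double s = 0.0; int n = 0;
      for (int k = 0; k < K; ++k) {
        int rr = r + odr[k], cc = c + odc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double zn = dem(rr, cc);
        if (NumericMatrix::is_na(zn)) continue;
        s += zn; ++n;
      }
      out(r, c) = (n > 0) ? z - s / n : NA_REAL;
    }
  }
  return out;
}

static const double DT_INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2004).
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -DT_INF; z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == DT_INF) continue;
    if (f[v[0]] == DT_INF) { v[0] = q; z[0] = -DT_INF; z[1] = DT_INF; continue; }
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = DT_INF;
  }
  if (f[v[0]] == DT_INF) { // no features at all in this line
    for (int q = 0; q < n; ++q) d[q] = DT_INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in cell units) from every cell centre to the
// nearest mask==1 cell centre. Mask cells get 0. Requires >= 1 mask cell.
// [[Rcpp::export]]
NumericMatrix edt_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // transform along columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r)
      f[r] = (mask(r, c) == 1) ? 0.0 : DT_INF;
    f.resize(nr); d.resize(nr);
    dt1d(f, d);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
    f.resize(std::max(nr, nc)); d.resize(std::max(nr, nc));
  }
  // transform along rows
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    f.resize(nc); d.resize(nc);
    dt1d(f, d);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
    f.resize(std::max(nr, nc)); d.resize(std::max(nr, nc));
  }
  return out;
}

// NA-aware block mean over k x k fine cells; partial blocks at the bottom/right
// edges average over the cells they cover. All-NA blocks get NA.
// [[Rcpp::export]]
NumericMatrix blockmean_cpp(NumericMatrix x, int k) {
  int nr = x.nrow(), nc = x.ncol();
  int NR = (nr + k - 1) / k, NC = (nc + k - 1) / k;
  NumericMatrix out(NR, NC);
  for (int R = 0; R < NR; ++R) {
    for (int C = 0; C < NC; ++C) {
      double s = 0.0; int n = 0;
      int r1 = R * k, r2 = std::min(nr, r1 + k);
      int c1 = C * k, c2 = std::min(nc, c1 + k);
      for (int r = r1; r < r2; ++r)
        for (int c = c1; c < c2; ++c) {
          double v = x(r, c);
          if (!NumericMatrix::is_na(v)) { s += v; ++n; }
        }
      out(R, C) = (n > 0) ? s / n : NA_REAL;
    }
  }
  return out;
}
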