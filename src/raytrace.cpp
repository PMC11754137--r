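#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Parametric (Siddon-style) traversal of a segment through a regular 2D grid.
// Grid: nx x ny pixels of size h, lower-left corner at (xmin, ymin).
// Pixel (ix, iy), 0-based, covers the half-open cell
// [xmin + ix*h, xmin + (ix+1)*h) x [ymin + iy*h, ymin + (iy+1)*h).
// Linear pixel index k0 = ix + nx*iy (0-based).
//
// Strategy: clip the segment to the grid box, collect every crossing of a
// pixel boundary as a parameter t in (t0, t1), and assign each resulting
// sub-interval to the pixel containing its midpoint. Robust at corners and
// for axis-aligned rays; zero-length intervals are dropped.
static void trace_core(int nx, int ny, double h, double xmin, double ymin,
                       double x0, double y0, double x1, double y1,
                       std::vector<int> &idx, std::vector<double> &len) {
  const double dx = x1 - x0, dy = y1 - y0;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return;
  const double xmax = xmin + nx * h, ymax = ymin + ny * h;

  double t0 = 0.0, t1 = 1.0;
  if (dx != 0.0) {
    double ta = (xmin - x0) / dx, tb = (xmax - x0) / dx;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
  } else if (x0 < xmin || x0 >= xmax) {
    return;
  }
  if (dy != 0.0) {
    double ta = (ymin - y0) / dy, tb = (ymax - y0) / dy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
  } else if (y0 < ymin || y0 >= ymax) {
    return;
  }
  if (!(t1 > t0)) return;

  // x- and y-plane crossings inside (t0, t1), each naturally sorted.
  std::vector<double> tx, ty;
  if (dx != 0.0) {
    int i_lo = (int)std::ceil((std::min(x0 + t0 * dx, x0 + t1 * dx) - xmin) / h);
    int i_hi = (int)std::floor((std::max(x0 + t0 * dx, x0 + t1 * dx) - xmin) / h);
    i_lo = std::max(i_lo, 0);
    i_hi = std::min(i_hi, nx);
    for (int i = i_lo; i <= i_hi; ++i) {
      double t = (xmin + i * h - x0) / dx;
      if (t > t0 && t < t1) tx.push_back(t);
    }
    if (dx < 0) std::reverse(tx.begin(), tx.end());
  }
  if (dy != 0.0) {
    int j_lo = (int)std::ceil((std::min(y0 + t0 * dy, y0 + t1 * dy) - ymin) / h);
    int j_hi = (int)std::floor((std::max(y0 + t0 * dy, y0 + t1 * dy) - ymin) / h);
    j_lo = std::max(j_lo, 0);
    j_hi = std::min(j_hi, ny);
    for (int j = j_lo; j <= j_hi; ++j) {
      double t = (ymin + j * h - y0) / dy;
      if (t > t0 && t < t1) ty.push_back(t);
    }
    if (dy < 0) std::reverse(ty.begin(), ty.end());
  }

  // Merge the two sorted crossing lists with t0/t1 as end points.
  std::vector<double> ts;
  ts.reserve(tx.size() + ty.size() + 2);
  ts.push_back(t0);
  size_t a = 0, b = 0;
  while (a < tx.size() || b < ty.size()) {
    double v;
    if (a < tx.size() && (b >= ty.size() || tx[a] <= ty[b])) v = tx[a++];
    else v = ty[b++];
    if (v > ts.back() + 1e-15) ts.push_back(v);
  }
  if (t1 > ts.back() + 1e-15) ts.push_back(t1);
  else ts.back() = t1;

  for (size_t s = 0; s + 1 < ts.size(); ++s) {
    double ta = ts[s], tb = ts[s + 1];
    double seg = (tb - ta) * L;
    if (seg <= 0.0) continue;
    double tm = 0.5 * (ta + tb);
    int ix = (int)std::floor((x0 + tm * dx - xmin) / h);
    int iy = (int)std::floor((y0 + tm * dy - ymin) / h);
    if (ix < 0) ix = 0; else if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; else if (iy >= ny) iy = ny - 1;
    idx.push_back(ix + nx * iy);
    len.push_back(seg);
  }
}

// [[Rcpp::export]]
List cpp_trace_ray(int nx, int ny, double h, double xmin, double ymin,
                   NumericVector p0, NumericVector p1) {
  std::vector<int> idx;
  std::vector<double> len;
  trace_core(nx, ny, h, xmin, ymin, p0[0], p0[1], p1[0], p1[1], idx, len);
  IntegerVector k(idx.size());
  NumericVector l(len.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    k[i] = idx[i] + 1;  // 1-based for R
    l[i] = len[i];
  }
  return List::create(_["index"] = k, _["length"] = l);
}

// Build sparse path-operator triplets for all source-receiver pairs.
// Row r (1-based) = (n-1)*M + m for source n, receiver m.
// [[Rcpp::export]]
List cpp_build_operator(int nx, int ny, double h, double xmin, double ymin,
                        NumericMatrix sources, NumericMatrix receivers) {
  const int N = sources.nrow(), M = receivers.nrow();
  std::vector<int> ri, ci;
  std::vector<double> xv;
  NumericVector total_len(N * M), ingrid_len(N * M);
  std::vector<int> idx;
  std::vector<double> len;
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      idx.clear();
      len.clear();
      double x0 = sources(n, 0), y0 = sources(n, 1);
      double x1 = receivers(m, 0), y1 = receivers(m, 1);
      trace_core(nx, ny, h, xmin, ymin, x0, y0, x1, y1, idx, len);
      int r = n * M + m;
      double dx = x1 - x0, dy = y1 - y0;
      total_len[r] = std::sqrt(dx * dx + dy * dy);
      double s = 0.0;
      for (size_t q = 0; q < idx.size(); ++q) {
        ri.push_back(r + 1);
        ci.push_back(idx[q] + 1);
        xv.push_back(len[q]);
        s += len[q];
      }
      ingrid_len[r] = s;
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(xv),
                      _["total_len"] = total_len, _["ingrid_len"] = ingrid_len);
}

// Straight-ray travel times from every receiver to every field point through
// a slowness map; the out-of-grid part of each segment travels at 1/s0.
// Returns a P x M matrix (field points in rows, receivers in columns).
// [[Rcpp::export]]
NumericMatrix cpp_tof_points(int nx, int ny, double h, double xmin, double ymin,
                             NumericVector slowness, double s0,
                             NumericMatrix receivers, NumericMatrix points) {
  const int M = receivers.nrow(), P = points.nrow();
  NumericMatrix out(P, M);
  std::vector<int> idx;
  std::vector<double> len;
  for (int m = 0; m < M; ++m) {
    double x1 = receivers(m, 0), y1 = receivers(m, 1);
    for (int p = 0; p < P; ++p) {
      idx.clear();
      len.clear();
      double x0 = points(p, 0), y0 = points(p, 1);
      trace_core(nx, ny, h, xmin, ymin, x0, y0, x1, y1, idx, len);
      double tin = 0.0, lin = 0.0;
      for (size_t q = 0; q < idx.size(); ++q) {
        tin += len[q] * slowness[idx[q]];
        lin += len[q];
      }
      double dx = x1 - x0, dy = y1 - y0;
      double L = std::sqrt(dx * dx + dy * dy);
      out(p, m) = tin + (L - lin) * s0;
    }
  }
  return out;
}
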