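#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// First-order fast marching solver for the eikonal equation |grad T| = s(x)
// on a node-centered regular grid: node (i, j) at (xmin + i*h, ymin + j*h),
// 0-based, linear index i + nx*j. The source singularity is handled by
// initializing T analytically (distance times local slowness) on all nodes
// within init_radius*h of the source.
//
// Returns the travel-time field T as a vector of length nx*ny.
// [[Rcpp::export]]
NumericVector cpp_fmm(int nx, int ny, double h, double xmin, double ymin,
                      NumericVector slowness,
                      double src_x, double src_y, double init_radius) {
  const double INF = std::numeric_limits<double>::infinity();
  const int K = nx * ny;
  std::vector<double> T(K, INF);
  std::vector<char> state(K, 0);  // 0 far, 1 trial, 2 known

  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > heap;

  // Nearest node to the source carries the local slowness used for the
  // analytic initialization disc.
  int si = (int)std::lround((src_x - xmin) / h);
  int sj = (int)std::lround((src_y - ymin) / h);
  if (si < 0 || si >= nx || sj < 0 || sj >= ny)
    stop("source lies outside the solver domain");
  double s_src = slowness[si + nx * sj];

  double r0 = init_radius * h;
  int ilo = std::max(0, (int)std::floor((src_x - r0 - xmin) / h));
  int ihi = std::min(nx - 1, (int)std::ceil((src_x + r0 - xmin) / h));
  int jlo = std::max(0, (int)std::floor((src_y - r0 - ymin) / h));
  int jhi = std::min(ny - 1, (int)std::ceil((src_y + r0 - ymin) / h));
  for (int j = jlo; j <= jhi; ++j) {
    for (int i = ilo; i <= ihi; ++i) {
      double dx = xmin + i * h - src_x, dy = ymin + j * h - src_y;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d <= r0) {
        int k = i + nx * j;
        T[k] = d * s_src;
        state[k] = 2;
      }
    }
  }

  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};

  // Upwind update of node (i, j) from its known neighbors.
  // Solves (T - a)^2 + (T - b)^2 = h^2 s^2 with a, b the smaller known
  // neighbor values along x and y.
  struct Upd {
    int nx, ny;
    double h;
    const std::vector<double> *T;
    double operator()(int i, int j, double s) const {
      const std::vector<double> &Tv = *T;
      double a = std::numeric_limits<double>::infinity();
      double b = a;
      if (i > 0) a = std::min(a, Tv[i - 1 + nx * j]);
      if (i < nx - 1) a = std::min(a, Tv[i + 1 + nx * j]);
      if (j > 0) b = std::min(b, Tv[i + nx * (j - 1)]);
      if (j < ny - 1) b = std::min(b, Tv[i + nx * (j + 1)]);
      double hs = h * s;
      if (!std::isfinite(a) && !std::isfinite(b))
        return std::numeric_limits<double>::infinity();
      if (!std::isfinite(b)) return a + hs;
      if (!std::isfinite(a)) return b + hs;
      if (std::fabs(a - b) >= hs) return std::min(a, b) + hs;
      double disc = 2.0 * hs * hs - (a - b) * (a - b);
      return 0.5 * (a + b + std::sqrt(disc));
    }
  };
  Upd update;
  update.nx = nx;
  update.ny = ny;
  update.h = h;
  update.T = &T;

  // Seed the band around the initialized disc.
  for (int j = jlo; j <= jhi; ++j) {
    for (int i = ilo; i <= ihi; ++i) {
      if (state[i + nx * j] != 2) continue;
      for (int q = 0; q < 4; ++q) {
        int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        int kk = ii + nx * jj;
        if (state[kk] == 2) continue;
        double t = update(ii, jj, slowness[kk]);
        if (t < T[kk]) {
          T[kk] = t;
          state[kk] = 1;
          heap.push(QN(t, kk));
        }
      }
    }
  }

  while (!heap.empty()) {
    QN top = heap.top();
    heap.pop();
    int k = top.second;
    if (state[k] == 2 || top.first > T[k]) continue;  // stale entry
    state[k] = 2;
    int i = k % nx, j = k / nx;
    for (int q = 0; q < 4; ++q) {
      int ii = i + di[q], jj = j + dj[q];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
      int kk = ii + nx * jj;
      if (state[kk] == 2) continue;
      double t = update(ii, jj, slowness[kk]);
      if (t < T[kk]) {
        T[kk] = t;
        state[kk] = 1;
        heap.push(QN(t, kk));
      }
    }
  }

  return wrap(T);
}
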