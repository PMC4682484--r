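#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

inline double wrap(double v, double W) {
  v -= W * std::floor(v / W);
  if (v >= W) v -= W;   // guard against rounding at the boundary
  return v;
}
inline double mi(double d, double W) { // minimum-image component difference
  if (d > 0.5 * W) return d - W;
  if (d < -0.5 * W) return d + W;
  return d;
}

struct Grid {
  int n; double W, h;
  std::vector<std::vector<int>> cells;
  void init(double W_, double rmax) {
    W = W_;
    n = std::max(1, (int)std::floor(W / (2.5 * rmax)));
    n = std::min(n, 128);
    h = W / n;
    cells.assign((size_t)n * n, {});
  }
  int cell(double x, double y) const {
    int i = (int)std::floor(x / h) % n, j = (int)std::floor(y / h) % n;
    if (i < 0) i += n; if (j < 0) j += n;
    return j * n + i;
  }
  void insert(int k, double x, double y) { cells[cell(x, y)].push_back(k); }
  template <class F> void neighbors(double x, double y, F f) const {
    int ci = (int)std::floor(x / h), cj = (int)std::floor(y / h);
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
      int i = (ci + di) % n, j = (cj + dj) % n;
      if (i < 0) i += n; if (j < 0) j += n;
      for (int k : cells[(size_t)j * n + i]) f(k);
    }
  }
};

} // namespace

// Random sequential addition followed by collective-rearrangement relaxation.
// Returns centers plus diagnostics; caller decides whether the achieved
// configuration is acceptable.
//' @noRd
// [[Rcpp::export(name = ".pack_disks_cpp")]]
List pack_disks_cpp(NumericVector radii, double W, int rsa_tries, int relax_sweeps) {
  const int n = radii.size();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  if (2.0 * rmax >= 0.5 * W) stop("tile too small relative to largest cylinder");

  // place largest first
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return radii[a] > radii[b]; });

  std::vector<double> px(n), py(n);
  std::vector<bool> placed(n, false);
  RNGScope scope;
  Grid grid; grid.init(W, rmax);

  int n_rsa = 0;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    bool ok = false;
    for (int t = 0; t < rsa_tries && !ok; ++t) {
      double x = unif_rand() * W, y = unif_rand() * W;
      bool clash = false;
      grid.neighbors(x, y, [&](int k) {
        if (clash) return;
        double dx = mi(px[k] - x, W), dy = mi(py[k] - y, W);
        double s = radii[k] + radii[i];
        if (dx * dx + dy * dy < s * s) clash = true;
      });
      if (!clash) { px[i] = x; py[i] = y; ok = true; }
    }
    if (!ok) { px[i] = unif_rand() * W; py[i] = unif_rand() * W; }
    else ++n_rsa;
    placed[i] = true;
    grid.insert(i, px[i], py[i]);
  }

  // relaxation: push overlapping pairs apart until feasible
  int sweeps_used = 0;
  double worst = 1.0;
  for (int sw = 0; sw < relax_sweeps; ++sw) {
    // rebuild grid
    grid.init(W, rmax);
    for (int i = 0; i < n; ++i) grid.insert(i, px[i], py[i]);
    bool any = false;
    worst = 1.0;
    for (int i = 0; i < n; ++i) {
      grid.neighbors(px[i], py[i], [&](int k) {
        if (k <= i) return;
        double dx = mi(px[k] - px[i], W), dy = mi(py[k] - py[i], W);
        double d = std::sqrt(dx * dx + dy * dy);
        double s = radii[i] + radii[k];
        if (d < s * (1.0 - 1e-12)) {
          any = true;
          worst = std::min(worst, d / s);
          double push;
          if (d < 1e-9 * s) { // coincident: split along random direction
            double th = unif_rand() * 2.0 * M_PI;
            dx = std::cos(th); dy = std::sin(th); d = 1.0;
            push = 0.55 * s;
          } else {
            push = 0.5 * (s - d) * 1.05;
          }
          double ux = dx / d, uy = dy / d;
          px[i] = wrap(px[i] - ux * push, W); py[i] = wrap(py[i] - uy * push, W);
          px[k] = wrap(px[k] + ux * push, W); py[k] = wrap(py[k] + uy * push, W);
        }
      });
    }
    sweeps_used = sw + 1;
    if (!any) break;
  }

  // final overlap audit
  grid.init(W, rmax);
  for (int i = 0; i < n; ++i) grid.insert(i, px[i], py[i]);
  double min_ratio = 1.0;
  for (int i = 0; i < n; ++i) {
    grid.neighbors(px[i], py[i], [&](int k) {
      if (k <= i) return;
      double dx = mi(px[k] - px[i], W), dy = mi(py[k] - py[i], W);
      double d = std::sqrt(dx * dx + dy * dy);
      min_ratio = std::min(min_ratio, d / (radii[i] + radii[k]));
    });
  }

  NumericMatrix centers(n, 2);
  for (int i = 0; i < n; ++i) { centers(i, 0) = px[i]; centers(i, 1) = py[i]; }
  return List::create(_["centers"] = centers,
                      _["feasible"] = (min_ratio >= 1.0 - 1e-9),
                      _["min_gap_ratio"] = min_ratio,
                      _["n_rsa"] = n_rsa,
                      _["sweeps"] = sweeps_used);
}

// distance from each pixel centre to the nearest cylinder wall
// (negative inside a cylinder), periodic minimum image
//' @noRd
// [[Rcpp::export(name = ".dist_to_walls_cpp")]]
NumericVector dist_to_walls_cpp(int nx, int ny, double W, double H,
                                NumericMatrix centers, NumericVector radii) {
  const int n = centers.nrow();
  NumericVector out((size_t)nx * ny);
  for (int j = 0; j < ny; ++j) {
    double y = (j + 0.5) * H / ny;
    for (int i = 0; i < nx; ++i) {
      double x = (i + 0.5) * W / nx;
      double best = R_PosInf;
      for (int k = 0; k < n; ++k) {
        double dx = mi(centers(k, 0) - x, W), dy = mi(centers(k, 1) - y, H);
        double d = std::sqrt(dx * dx + dy * dy) - radii[k];
        if (d < best) best = d;
      }
      out[(size_t)j * nx + i] = best;
    }
  }
  return out;
}
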