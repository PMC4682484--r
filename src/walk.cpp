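#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Circle { double x, y, r; };

// uniform grid over the periodic box; each cell lists circles (incl. images)
// whose inflated disc can touch a step that starts in the cell
struct CircleGrid {
  int nx, ny;
  double W, H, hx, hy;
  std::vector<std::vector<int>> cells;
  std::vector<Circle> circ;

  void build(const NumericMatrix& centers, const NumericVector& radii,
             double W_, double H_, bool periodic, double reach) {
    W = W_; H = H_;
    double rmax = 0.0;
    for (int i = 0; i < radii.size(); ++i) rmax = std::max(rmax, radii[i]);
    double margin = periodic ? (rmax + reach) : 0.0;
    circ.clear();
    for (int i = 0; i < centers.nrow(); ++i) {
      double cx = centers(i, 0), cy = centers(i, 1), r = radii[i];
      int sxlo = 0, sxhi = 0, sylo = 0, syhi = 0;
      if (periodic) {
        sxlo = (cx - r - margin < 0.0) ? -0 : 0; // images handled below
      }
      // add base + any periodic images whose disc reaches into [−margin, W+margin)
      for (int sx = -1; sx <= 1; ++sx) for (int sy = -1; sy <= 1; ++sy) {
        if (!periodic && (sx || sy)) continue;
        double ix = cx + sx * W, iy = cy + sy * H;
        if (ix + r < -margin || ix - r > W + margin ||
            iy + r < -margin || iy - r > H + margin) continue;
        circ.push_back({ix, iy, r});
      }
      (void)sxlo; (void)sxhi; (void)sylo; (void)syhi;
    }
    nx = std::max(1, (int)std::floor(W / std::max(1e-12, 2.0 * (rmax + reach))));
    ny = std::max(1, (int)std::floor(H / std::max(1e-12, 2.0 * (rmax + reach))));
    nx = std::min(nx, 256); ny = std::min(ny, 256);
    hx = W / nx; hy = H / ny;
    cells.assign((size_t)nx * ny, {});
    double diag = 0.5 * std::sqrt(hx * hx + hy * hy);
    for (int k = 0; k < (int)circ.size(); ++k) {
      const Circle& c = circ[k];
      double rad = c.r + reach + diag;
      int i0 = (int)std::floor((c.x - rad) / hx), i1 = (int)std::floor((c.x + rad) / hx);
      int j0 = (int)std::floor((c.y - rad) / hy), j1 = (int)std::floor((c.y + rad) / hy);
      for (int i = i0; i <= i1; ++i) for (int j = j0; j <= j1; ++j) {
        if (i < 0 || i >= nx || j < 0 || j >= ny) continue;
        double ccx = (i + 0.5) * hx, ccy = (j + 0.5) * hy;
        double dx = ccx - c.x, dy = ccy - c.y;
        if (std::sqrt(dx * dx + dy * dy) <= c.r + reach + diag)
          cells[(size_t)j * nx + i].push_back(k);
      }
    }
  }

  const std::vector<int>& lookup(double x, double y) const {
    int i = (int)std::floor(x / hx), j = (int)std::floor(y / hy);
    i = std::min(std::max(i, 0), nx - 1);
    j = std::min(std::max(j, 0), ny - 1);
    return cells[(size_t)j * nx + i];
  }
};

// advance one walker by one fixed-length step with specular reflections.
// inside==true: walker confined inside circle 0 (intracylinder);
// inside==false: walker excluded from all circles (EAS).
// Returns false if the reflection budget is exhausted.
inline bool advance(double& x, double& y, double ux, double uy, double len,
                    const CircleGrid& grid, bool inside, int max_bounce) {
  double px = x, py = y;
  double dx = ux * len, dy = uy * len;
  int b;
  for (b = 0; b <= max_bounce; ++b) {
    double best_t = 2.0; int best_k = -1;
    const std::vector<int>& cand = grid.lookup(
      std::min(std::max(px, 0.0), grid.W * (1.0 - 1e-16)),
      std::min(std::max(py, 0.0), grid.H * (1.0 - 1e-16)));
    for (int idx = 0; idx < (int)cand.size(); ++idx) {
      const Circle& c = grid.circ[cand[idx]];
      double ox = c.x - px, oy = c.y - py;
      double a = dx * dx + dy * dy;
      if (a <= 0.0) break;
      double tc = (ox * dx + oy * dy) / a;
      double d2 = ox * ox + oy * oy - tc * tc * a;
      double disc = c.r * c.r - d2;
      if (disc < 0.0) continue;
      double sq = std::sqrt(disc / a);
      double t = inside ? (tc + sq) : (tc - sq);
      if (t > 1e-12 && t < 1.0 && t < best_t) { best_t = t; best_k = cand[idx]; }
    }
    if (best_k < 0) { x = px + dx; y = py + dy; return true; }
    const Circle& c = grid.circ[best_k];
    double hx_ = px + best_t * dx, hy_ = py + best_t * dy;
    double nxv = (hx_ - c.x) / c.r, nyv = (hy_ - c.y) / c.r;
    double rx = (1.0 - best_t) * dx, ry = (1.0 - best_t) * dy;
    double dot = rx * nxv + ry * nyv;
    rx -= 2.0 * dot * nxv; ry -= 2.0 * dot * nyv;
    double side = inside ? -1.0 : 1.0;
    px = hx_ + side * 1e-9 * c.r * nxv;
    py = hy_ + side * 1e-9 * c.r * nyv;
    dx = rx; dy = ry;
  }
  // grazing chatter: many near-tangent bounces each consuming almost no path.
  // If the unresolved remainder is a negligible fraction of the step, absorb
  // it at the wall; otherwise report failure.
  if (std::sqrt(dx * dx + dy * dy) < 0.1 * len) { x = px; y = py; return true; }
  return false;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_walk_cpp")]]
List mc_walk_cpp(NumericMatrix centers, NumericVector radii,
                 double W, double H, bool periodic, bool intracyl,
                 NumericVector x0, NumericVector y0,
                 double step_len, int nsteps,
                 NumericMatrix gmat, double dt,
                 int record_every) {
  const int nw = x0.size();
  const int K = gmat.ncol();
  if (gmat.nrow() != nsteps) stop("gradient matrix must have one row per step");
  CircleGrid grid;
  bool has_circ = centers.nrow() > 0;
  if (has_circ) grid.build(centers, radii, W, H, periodic && !intracyl, 2.0 * step_len);

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> offx(nw, 0.0), offy(nw, 0.0);
  NumericMatrix phase(nw, K);
  int nrec = (record_every > 0) ? (nsteps / record_every) : 0;
  NumericMatrix recx(nrec > 0 ? nw : 0, nrec), recy(nrec > 0 ? nw : 0, nrec);

  RNGScope scope;
  std::vector<double> grow(K);
  int irec = 0;
  for (int i = 0; i < nsteps; ++i) {
    for (int k = 0; k < K; ++k) grow[k] = gmat(i, k) * dt;
    for (int j = 0; j < nw; ++j) {
      double th = unif_rand() * 2.0 * M_PI;
      double xx = x[j], yy = y[j];
      if (has_circ) {
        if (!advance(xx, yy, std::cos(th), std::sin(th), step_len, grid,
                     intracyl, 64))
          stop("walker reflection budget exceeded (step %d); geometry too tight for step length", i + 1);
      } else {
        xx += step_len * std::cos(th); yy += step_len * std::sin(th);
      }
      if (periodic && !intracyl) {
        if (xx < 0.0)      { xx += W; offx[j] -= W; }
        else if (xx >= W)  { xx -= W; offx[j] += W; }
        if (yy < 0.0)      { yy += H; offy[j] -= H; }
        else if (yy >= H)  { yy -= H; offy[j] += H; }
      }
      x[j] = xx; y[j] = yy;
      double xu = xx + offx[j];
      for (int k = 0; k < K; ++k) phase(j, k) += grow[k] * xu;
    }
    if (record_every > 0 && ((i + 1) % record_every == 0) && irec < nrec) {
      for (int j = 0; j < nw; ++j) { recx(j, irec) = x[j]; recy(j, irec) = y[j]; }
      ++irec;
    }
  }

  NumericVector xf(nw), yf(nw);
  for (int j = 0; j < nw; ++j) { xf[j] = x[j] + offx[j]; yf[j] = y[j] + offy[j]; }
  List out = List::create(_["phase"] = phase, _["x_final"] = xf, _["y_final"] = yf);
  if (nrec > 0) { out["rec_x"] = recx; out["rec_y"] = recy; }
  return out;
}
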