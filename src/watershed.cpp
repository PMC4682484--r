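#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
using namespace Rcpp;

// Watershed-by-immersion of a field on a periodic grid, restricted to mask.
// Pixels are processed in decreasing field order; a pixel with no labelled
// neighbour seeds a basin, otherwise it joins the labelled neighbour with the
// highest field value. The first contact between two basins records the ridge
// saddle height (maximal, since processing is ordered).
//' @noRd
// [[Rcpp::export(name = ".watershed_cpp")]]
List watershed_cpp(NumericVector field, LogicalVector mask, int nx, int ny) {
  const size_t npix = (size_t)nx * ny;
  if (field.size() != (R_xlen_t)npix || mask.size() != (R_xlen_t)npix)
    stop("field/mask size mismatch");
  std::vector<size_t> idx;
  idx.reserve(npix);
  for (size_t i = 0; i < npix; ++i) if (mask[i]) idx.push_back(i);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](size_t a, size_t b) { return field[a] > field[b]; });

  std::vector<int> label(npix, 0);
  std::vector<double> peak;   // peak height per basin (1-based labels)
  peak.push_back(0.0);        // dummy for label 0
  std::map<std::pair<int, int>, double> ridge;

  const int dxs[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dys[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

  for (size_t t = 0; t < idx.size(); ++t) {
    size_t p = idx[t];
    int px = (int)(p % nx), py = (int)(p / nx);
    int best_lab = 0; double best_val = -1.0;
    int labs[8]; int nlab = 0;
    for (int q = 0; q < 8; ++q) {
      int qx = px + dxs[q], qy = py + dys[q];
      if (qx < 0) qx += nx; else if (qx >= nx) qx -= nx;
      if (qy < 0) qy += ny; else if (qy >= ny) qy -= ny;
      size_t pq = (size_t)qy * nx + qx;
      int l = label[pq];
      if (l > 0) {
        bool seen = false;
        for (int s = 0; s < nlab; ++s) if (labs[s] == l) { seen = true; break; }
        if (!seen) labs[nlab++] = l;
        if (field[pq] > best_val) { best_val = field[pq]; best_lab = l; }
      }
    }
    if (best_lab == 0) {
      peak.push_back(field[p]);
      label[p] = (int)peak.size() - 1;
    } else {
      label[p] = best_lab;
      for (int s = 0; s < nlab; ++s) {
        if (labs[s] == best_lab) continue;
        int a = std::min(labs[s], best_lab), b = std::max(labs[s], best_lab);
        auto key = std::make_pair(a, b);
        if (ridge.find(key) == ridge.end()) ridge[key] = field[p];
      }
    }
  }

  int npairs = (int)ridge.size();
  IntegerVector ra(npairs), rb(npairs);
  NumericVector rs(npairs);
  int k = 0;
  for (auto& kv : ridge) { ra[k] = kv.first.first; rb[k] = kv.first.second; rs[k] = kv.second; ++k; }
  IntegerVector lab(npix);
  for (size_t i = 0; i < npix; ++i) lab[i] = label[i];
  NumericVector pk(peak.size() - 1);
  for (size_t i = 1; i < peak.size(); ++i) pk[i - 1] = peak[i];
  return List::create(_["label"] = lab, _["peak"] = pk,
                      _["ridge_a"] = ra, _["ridge_b"] = rb, _["ridge_saddle"] = rs);
}
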