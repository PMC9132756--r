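#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement over an arbitrary voxel subset.
//
// values:  statistic per mask voxel (only the positive part contributes)
// coords:  p x 3 matrix of 0-based voxel coordinates
// shape:   grid dimensions
// For each threshold h = dh, 2dh, ... <= max(values), connected components
// of { v : values[v] >= h } are labelled with a flood fill restricted to the
// mask, and every suprathreshold voxel accumulates size^E * h^H * dh.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerMatrix coords,
                       IntegerVector shape, double E, double H, double dh,
                       int connectivity) {
  const int p = values.size();
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  NumericVector out(p);
  double hmax = 0.0;
  for (int i = 0; i < p; ++i) if (values[i] > hmax) hmax = values[i];
  if (hmax <= 0.0 || dh <= 0.0) return out;

  // linear-index lookup: voxel -> position in the mask vectors
  std::vector<int> lut((size_t)nx * ny * nz, -1);
  std::vector<int> lin(p);
  for (int i = 0; i < p; ++i) {
    int x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    int li = x + nx * (y + ny * z);
    lin[i] = li;
    lut[li] = i;
  }

  // neighbourhood offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nn = (int)dxs.size();

  std::vector<int> comp(p), stack;
  std::vector<int> members;
  const int nsteps = (int)std::floor(hmax / dh + 1e-12);
  const double eps = 1e-12 * hmax;   // guard against h = step*dh rounding up
  for (int step = 1; step <= nsteps; ++step) {
    double h = step * dh - eps;
    std::fill(comp.begin(), comp.end(), -1);
    int ncomp = 0;
    for (int i = 0; i < p; ++i) {
      if (values[i] < h || comp[i] >= 0) continue;
      // flood fill component ncomp
      members.clear();
      stack.clear();
      stack.push_back(i);
      comp[i] = ncomp;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        members.push_back(v);
        int x = coords(v, 0), y = coords(v, 1), z = coords(v, 2);
        for (int k = 0; k < nn; ++k) {
          int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int w = lut[xx + nx * (yy + (size_t)ny * zz)];
          if (w < 0 || comp[w] >= 0 || values[w] < h) continue;
          comp[w] = ncomp;
          stack.push_back(w);
        }
      }
      double add = std::pow((double)members.size(), E) * std::pow(h, H) * dh;
      for (size_t k = 0; k < members.size(); ++k) out[members[k]] += add;
      ++ncomp;
    }
  }
  return out;
}
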