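#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling on a 0/1 volume.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns an integer volume: 0 for background, 1..K component labels,
// labelled in scan order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(NumericVector vol, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (vol[seed] == 0 || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (vol[j] != 0 && labels[j] == 0) {
          labels[j] = current;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Directed max-min surface distance support: for every point of A,
// the minimum Euclidean distance to any point of B. Coordinates are
// given in physical units (mm), one row per point.
// [[Rcpp::export(name = ".min_distances")]]
NumericVector min_distances(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double d0 = ax - b(j, 0), d1 = ay - b(j, 1), d2 = az - b(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
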