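#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void neighbourOffsets(int connectivity,
                             std::vector<int>& dx,
                             std::vector<int>& dy,
                             std::vector<int>& dz) {
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        bool keep = (connectivity == 26) ||
                    (connectivity == 18 && m <= 2) ||
                    (connectivity == 6  && m == 1);
        if (keep) { dx.push_back(cx); dy.push_back(cy); dz.push_back(cz); }
      }
}

static int floodLabel(const std::vector<char>& in, std::vector<int>& lab,
                      int nx, int ny, int nz,
                      const std::vector<int>& dx, const std::vector<int>& dy,
                      const std::vector<int>& dz, std::vector<int>& sizes) {
  int n = nx * ny * nz;
  std::fill(lab.begin(), lab.end(), 0);
  sizes.clear();
  sizes.push_back(0); // sizes[0] unused
  std::vector<int> stack;
  int cur = 0;
  int nneigh = (int) dx.size();
  for (int i = 0; i < n; ++i) {
    if (!in[i] || lab[i]) continue;
    ++cur;
    int sz = 0;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++sz;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < nneigh; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (in[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
    sizes.push_back(sz);
  }
  return cur;
}

// Label 26/18/6-connected components of a 3D logical array.
// [[Rcpp::export(".labelComponentsCpp")]]
IntegerVector labelComponentsCpp(LogicalVector mask, IntegerVector dims,
                                 int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> in(n);
  for (int i = 0; i < n; ++i) in[i] = (mask[i] == TRUE);
  std::vector<int> dx, dy, dz;
  neighbourOffsets(connectivity, dx, dy, dz);
  std::vector<int> lab(n);
  std::vector<int> sizes;
  floodLabel(in, lab, nx, ny, nz, dx, dy, dz, sizes);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lab[i];
  out.attr("dim") = dims;
  return out;
}

// Threshold-free cluster enhancement of the positive side of a 3D map:
// TFCE(p) = sum over thresholds h = dh, 2dh, ... of e(h,p)^E * h^H * dh,
// where e(h,p) is the extent of the connected cluster (>= h) containing p.
// [[Rcpp::export(".tfceCpp")]]
NumericVector tfceCpp(NumericVector stat, IntegerVector dims,
                      double E, double H, double dh, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector out(n, 0.0);
  out.attr("dim") = dims;
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0.0 || dh <= 0.0) return out;

  std::vector<int> dx, dy, dz;
  neighbourOffsets(connectivity, dx, dy, dz);
  std::vector<char> in(n);
  std::vector<int> lab(n);
  std::vector<int> sizes;

  for (double h = dh; h <= hmax + 1e-12; h += dh) {
    bool any = false;
    for (int i = 0; i < n; ++i) {
      in[i] = (stat[i] >= h);
      any = any || in[i];
    }
    if (!any) break;
    int ncl = floodLabel(in, lab, nx, ny, nz, dx, dy, dz, sizes);
    if (ncl == 0) break;
    std::vector<double> add(ncl + 1, 0.0);
    double hh = std::pow(h, H) * dh;
    for (int c = 1; c <= ncl; ++c)
      add[c] = std::pow((double) sizes[c], E) * hh;
    for (int i = 0; i < n; ++i)
      if (lab[i]) out[i] += add[lab[i]];
  }
  return out;
}
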