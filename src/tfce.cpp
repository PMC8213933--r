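#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Neighborhood {
  std::vector<int> dx, dy, dz;
  explicit Neighborhood(int connectivity) {
    for (int z = -1; z <= 1; ++z)
      for (int y = -1; y <= 1; ++y)
        for (int x = -1; x <= 1; ++x) {
          if (x == 0 && y == 0 && z == 0) continue;
          if (connectivity == 6 && std::abs(x) + std::abs(y) + std::abs(z) > 1)
            continue;
          dx.push_back(x); dy.push_back(y); dz.push_back(z);
        }
  }
  size_t size() const { return dx.size(); }
};

// Label connected components of voxels where img >= thr.
// labels: 0 background, 1..n components; sizes collects voxel counts.
static int label_at_threshold(const double *img, int nx, int ny, int nz,
                              double thr, const Neighborhood &nb,
                              std::vector<int> &labels,
                              std::vector<int> &sizes) {
  const int n = nx * ny * nz;
  std::fill(labels.begin(), labels.end(), 0);
  sizes.clear();
  std::vector<int> stack;
  int ncomp = 0;
  for (int v = 0; v < n; ++v) {
    if (labels[v] != 0 || img[v] < thr) continue;
    ++ncomp;
    int size = 0;
    labels[v] = ncomp;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (size_t k = 0; k < nb.size(); ++k) {
        int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (labels[w] == 0 && img[w] >= thr) {
          labels[w] = ncomp;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(size);
  }
  return ncomp;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector img, IntegerVector dims,
                                   double threshold, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if ((int)img.size() != n) stop("image size does not match dims");
  Neighborhood nb(connectivity);
  std::vector<int> labels(n), sizes;
  label_at_threshold(REAL(img), nx, ny, nz, threshold, nb, labels, sizes);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = labels[i];
  out.attr("n_components") = (int)sizes.size();
  return out;
}

// Threshold-free cluster enhancement of the positive part of a 3D map:
// TFCE(v) = sum over thresholds h = dh, 2dh, ..., max of
//   extent(v, h)^E * h^H * dh,
// where extent(v, h) is the voxel count of the connected component
// containing v among voxels >= h. A map with no positive values returns
// all zeros.
// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector img, IntegerVector dims, double E,
                       double H, double dh, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if ((int)img.size() != n) stop("image size does not match dims");
  NumericVector out(n);
  double mx = 0;
  for (int i = 0; i < n; ++i) if (img[i] > mx) mx = img[i];
  if (mx <= 0) return out;
  if (dh <= 0) dh = mx / 100.0;
  int nsteps = (int)std::floor(mx / dh + 1e-7);
  if (nsteps < 1) nsteps = 1;
  Neighborhood nb(connectivity);
  std::vector<int> labels(n), sizes;
  std::vector<double> acc(n, 0.0);
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    int ncomp = label_at_threshold(REAL(img), nx, ny, nz, h, nb,
                                   labels, sizes);
    if (ncomp == 0) break;
    std::vector<double> contrib(ncomp);
    double hH = std::pow(h, H) * dh;
    for (int c = 0; c < ncomp; ++c)
      contrib[c] = std::pow((double)sizes[c], E) * hH;
    for (int v = 0; v < n; ++v)
      if (labels[v] > 0) acc[v] += contrib[labels[v] - 1];
  }
  for (int i = 0; i < n; ++i) out[i] = acc[i];
  return out;
}
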