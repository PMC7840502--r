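// Exact Euclidean distance transform on an anisotropic voxel grid,
// via the separable lower-envelope (parabola) algorithm applied per axis.
// Squared distances are computed everywhere from the given source voxels.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double BIG = 1e30; // stands in for +Inf; safe under squaring of grid extents

// 1D squared-distance transform with sample spacing w (f in place -> d).
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n, double w) {
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -BIG;
  zb[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s;
    bool replace_all = false;
    for (;;) {
      int vk = v[k];
      s = ((f[q] + (double)q * q * w2) - (f[vk] + (double)vk * vk * w2)) /
          (2.0 * w2 * (q - vk));
      if (s <= zb[k]) {
        if (k > 0) {
          k--;
        } else { // parabola q lies below v[0] over the whole line
          replace_all = true;
          break;
        }
      } else {
        break;
      }
    }
    if (replace_all) {
      k = 0;
      v[0] = q;
      zb[0] = -BIG;
      zb[1] = BIG;
    } else {
      k++;
      v[k] = q;
      zb[k] = s;
      zb[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zb[k + 1] < (double)q) k++;
    double dq = (double)(q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector source, IntegerVector dims,
                              NumericVector pitch_zyx) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = source[i] ? 0.0 : BIG;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (fastest-varying index)
  if (nz > 1) {
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) {
        R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = 0; z < nz; z++) f[z] = D[base + z];
        dt1d(f, d, v, zb, nz, pitch_zyx[0]);
        for (int z = 0; z < nz; z++) D[base + z] = d[z];
      }
    }
  }
  // pass along y
  if (ny > 1) {
    for (int x = 0; x < nx; x++) {
      for (int z = 0; z < nz; z++) {
        R_xlen_t base = z + (R_xlen_t)nz * ny * x;
        for (int y = 0; y < ny; y++) f[y] = D[base + (R_xlen_t)nz * y];
        dt1d(f, d, v, zb, ny, pitch_zyx[1]);
        for (int y = 0; y < ny; y++) D[base + (R_xlen_t)nz * y] = d[y];
      }
    }
  }
  // pass along x
  if (nx > 1) {
    const R_xlen_t sx = (R_xlen_t)nz * ny;
    for (int y = 0; y < ny; y++) {
      for (int z = 0; z < nz; z++) {
        R_xlen_t base = z + (R_xlen_t)nz * y;
        for (int x = 0; x < nx; x++) f[x] = D[base + sx * x];
        dt1d(f, d, v, zb, nx, pitch_zyx[2]);
        for (int x = 0; x < nx; x++) D[base + sx * x] = d[x];
      }
    }
  }
  D.attr("dim") = dims;
  return D;
}
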