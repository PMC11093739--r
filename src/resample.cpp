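#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim (nz, ny, nx), column-major: the linear
// index of voxel (z, y, x), all 0-based, is z + nz*y + nz*ny*x.
// M is a 3x4 voxel-space affine: src = M * (z, y, x, 1)'.

static inline bool trilinear(const double *v, int nz, int ny, int nx,
                             double sz, double sy, double sx, double &out) {
  if (sz < 0 || sy < 0 || sx < 0 ||
      sz > nz - 1 || sy > ny - 1 || sx > nx - 1)
    return false;
  int z0 = (int)std::floor(sz), y0 = (int)std::floor(sy),
      x0 = (int)std::floor(sx);
  if (z0 == nz - 1) z0--;
  if (y0 == ny - 1) y0--;
  if (x0 == nx - 1) x0--;
  if (nz == 1) z0 = 0;
  if (ny == 1) y0 = 0;
  if (nx == 1) x0 = 0;
  double fz = sz - z0, fy = sy - y0, fx = sx - x0;
  int z1 = nz == 1 ? z0 : z0 + 1, y1 = ny == 1 ? y0 : y0 + 1,
      x1 = nx == 1 ? x0 : x0 + 1;
  if (nz == 1) fz = 0;
  if (ny == 1) fy = 0;
  if (nx == 1) fx = 0;
#define V(z, y, x) v[(z) + (size_t)nz * ((y) + (size_t)ny * (x))]
  double c00 = V(z0, y0, x0) * (1 - fz) + V(z1, y0, x0) * fz;
  double c10 = V(z0, y1, x0) * (1 - fz) + V(z1, y1, x0) * fz;
  double c01 = V(z0, y0, x1) * (1 - fz) + V(z1, y0, x1) * fz;
  double c11 = V(z0, y1, x1) * (1 - fz) + V(z1, y1, x1) * fz;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  out = c0 * (1 - fx) + c1 * fx;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, double background) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out((size_t)nz * ny * nx);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double sz = M(0, 0) * z + M(0, 1) * y + M(0, 2) * x + M(0, 3);
        double sy = M(1, 0) * z + M(1, 1) * y + M(1, 2) * x + M(1, 3);
        double sx = M(2, 0) * z + M(2, 1) * y + M(2, 2) * x + M(2, 3);
        double val;
        o[z + (size_t)nz * (y + (size_t)ny * x)] =
            trilinear(v, nz, ny, nx, sz, sy, sx, val) ? val : background;
      }
  return out;
}

// Similarity between `fixed` and `moving` sampled through M over in-bounds
// voxels. type 0 = normalized cross-correlation, 1 = mutual information
// (nbins x nbins joint histogram, natural log). Returns -Inf when fewer
// than 10% of voxels overlap.
// [[Rcpp::export]]
double cpp_affine_metric(NumericVector fixed, NumericVector moving,
                         IntegerVector dim, NumericMatrix M, int type,
                         int nbins, double fmin, double fmax, double mmin,
                         double mmax, int stride) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double *f = fixed.begin(), *mv = moving.begin();
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  std::vector<double> joint;
  if (type == 1) joint.assign((size_t)nbins * nbins, 0.0);
  double frange = fmax > fmin ? fmax - fmin : 1.0;
  double mrange = mmax > mmin ? mmax - mmin : 1.0;
  long n = 0, total = 0;
  for (int x = 0; x < nx; x += stride)
    for (int y = 0; y < ny; y += stride)
      for (int z = 0; z < nz; z += stride) {
        ++total;
        double sz = M(0, 0) * z + M(0, 1) * y + M(0, 2) * x + M(0, 3);
        double sy = M(1, 0) * z + M(1, 1) * y + M(1, 2) * x + M(1, 3);
        double sx = M(2, 0) * z + M(2, 1) * y + M(2, 2) * x + M(2, 3);
        double val;
        if (!trilinear(mv, nz, ny, nx, sz, sy, sx, val)) continue;
        double fv = f[z + (size_t)nz * (y + (size_t)ny * x)];
        ++n;
        if (type == 0) {
          sf += fv; sm += val; sff += fv * fv; smm += val * val;
          sfm += fv * val;
        } else {
          int bi = (int)((fv - fmin) / frange * nbins);
          int bj = (int)((val - mmin) / mrange * nbins);
          if (bi < 0) bi = 0; if (bi >= nbins) bi = nbins - 1;
          if (bj < 0) bj = 0; if (bj >= nbins) bj = nbins - 1;
          joint[bi + (size_t)nbins * bj] += 1.0;
        }
      }
  if (n < total / 10 || n < 8) return R_NegInf;
  if (type == 0) {
    double vf = sff - sf * sf / n, vm = smm - sm * sm / n;
    if (vf <= 0 || vm <= 0) return R_NegInf;
    return (sfm - sf * sm / n) / std::sqrt(vf * vm);
  }
  std::vector<double> pi(nbins, 0.0), pj(nbins, 0.0);
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      double p = joint[i + (size_t)nbins * j] / n;
      pi[i] += p; pj[j] += p;
    }
  double mi = 0;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      double p = joint[i + (size_t)nbins * j] / n;
      if (p > 0) mi += p * std::log(p / (pi[i] * pj[j]));
    }
  return mi;
}
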