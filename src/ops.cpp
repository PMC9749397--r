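// Voxel-grid image operators: exact Euclidean distance transform (for
// millimetre mask dilation), separable Gaussian smoothing, and affine
// resampling with trilinear / nearest-neighbour interpolation.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// large finite stand-in for "no source on this line yet": keeps the parabola
// intersections finite while dominating any realistic squared distance
static const double DT_BIG = 1e15;
static const double DT_INF = std::numeric_limits<double>::infinity();

// 1-D squared-distance transform (lower envelope of parabolas) on a line
// sampled at spacing s; f holds squared distances on input and output.
static void dt1d(std::vector<double> &f, int n, double s,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    const double xq = q * s;
    double xv = v[k] * s;
    double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                 (2.0 * xq - 2.0 * xv);
    while (k > 0 && sep <= z[k]) {
      k--;
      xv = v[k] * s;
      sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
            (2.0 * xq - 2.0 * xv);
    }
    k++;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    const double xq = q * s;
    while (z[k + 1] < xq) k++;
    const double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (in mm) from every voxel to the nearest
// mask-positive voxel; honours anisotropic spacing.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = D * H * W;
  NumericVector out(N);
  for (int i = 0; i < N; i++) out[i] = mask[i] ? 0.0 : DT_BIG;

  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (fastest varying)
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++) {
      const int base = D * (h + H * w);
      for (int i = 0; i < D; i++) f[i] = out[base + i];
      dt1d(f, D, spacing[0], d, v, z);
      for (int i = 0; i < D; i++) out[base + i] = d[i];
    }
  // axis 1
  for (int w = 0; w < W; w++)
    for (int i = 0; i < D; i++) {
      for (int h = 0; h < H; h++) f[h] = out[i + D * (h + H * w)];
      dt1d(f, H, spacing[1], d, v, z);
      for (int h = 0; h < H; h++) out[i + D * (h + H * w)] = d[h];
    }
  // axis 2
  for (int h = 0; h < H; h++)
    for (int i = 0; i < D; i++) {
      for (int w = 0; w < W; w++) f[w] = out[i + D * (h + H * w)];
      dt1d(f, W, spacing[2], d, v, z);
      for (int w = 0; w < W; w++) out[i + D * (h + H * w)] = d[w];
    }
  return out;
}

// Separable Gaussian smoothing; kernel truncated at 4 sigma and renormalised
// over the in-bounds support, so constants are preserved exactly.
// [[Rcpp::export(name = ".cpp_gauss_blur")]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = D * H * W;
  NumericVector cur = clone(vol);
  NumericVector nxt(N);
  const int strides[3] = {1, D, D * H};
  const int extents[3] = {D, H, W};

  for (int ax = 0; ax < 3; ax++) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    int R = (int)std::ceil(4.0 * sg);
    std::vector<double> k(2 * R + 1);
    for (int j = -R; j <= R; j++)
      k[j + R] = std::exp(-0.5 * (double)(j * j) / (sg * sg));
    const int st = strides[ax];
    const int n = extents[ax];
    // iterate over all lines along this axis
    const int oth1 = (ax == 0) ? H : D;
    const int oth2 = (ax == 2) ? H : W;
    const int st1 = (ax == 0) ? D : 1;
    const int st2 = (ax == 2) ? D : D * H;
    for (int b = 0; b < oth2; b++)
      for (int a = 0; a < oth1; a++) {
        const int base = a * st1 + b * st2;
        for (int i = 0; i < n; i++) {
          double acc = 0.0, wsum = 0.0;
          int j0 = std::max(-R, -i), j1 = std::min(R, n - 1 - i);
          for (int j = j0; j <= j1; j++) {
            acc += k[j + R] * cur[base + (i + j) * st];
            wsum += k[j + R];
          }
          nxt[base + i * st] = acc / wsum;
        }
      }
    std::swap(cur, nxt);
  }
  return cur;
}

// Affine pull-back resampling: for each output voxel (0-based index p),
// sample the input at  q = M p + off  (voxel coordinates).
// interp: 0 = trilinear, 1 = nearest neighbour; fill outside the grid.
// [[Rcpp::export(name = ".cpp_resample_affine")]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dims,
                                  NumericMatrix M, NumericVector off,
                                  int interp, double fill) {
  const int D = dims[0], H = dims[1], W = dims[2];
  NumericVector out(D * H * W);
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++)
      for (int d = 0; d < D; d++) {
        const double x = m00 * d + m01 * h + m02 * w + off[0];
        const double y = m10 * d + m11 * h + m12 * w + off[1];
        const double z = m20 * d + m21 * h + m22 * w + off[2];
        const int idx = d + D * (h + H * w);
        if (interp == 1) {
          const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                    zi = (int)std::lround(z);
          out[idx] = (xi >= 0 && xi < D && yi >= 0 && yi < H &&
                      zi >= 0 && zi < W)
                         ? vol[xi + D * (yi + H * zi)]
                         : fill;
        } else {
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                    z0 = (int)std::floor(z);
          if (x0 < -1 || x0 >= D || y0 < -1 || y0 >= H || z0 < -1 ||
              z0 >= W) {
            out[idx] = fill;
            continue;
          }
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; dz++)
            for (int dy = 0; dy <= 1; dy++)
              for (int dx = 0; dx <= 1; dx++) {
                const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
                const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                const double val =
                    (xi >= 0 && xi < D && yi >= 0 && yi < H && zi >= 0 &&
                     zi < W)
                        ? vol[xi + D * (yi + H * zi)]
                        : fill;
                acc += wgt * val;
              }
          out[idx] = acc;
        }
      }
  return out;
}
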