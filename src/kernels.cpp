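#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// reflect an out-of-range 0-based index into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 3D median filter, cubic kernel k x k x k (k odd), reflective boundaries.
// [[Rcpp::export]]
NumericVector median_filter3_cpp(NumericVector x, IntegerVector dim, int k) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int r = k / 2;
  const int m = k * k * k;
  NumericVector out(x.size());
  std::vector<double> buf(m);
  for (int z = 0; z < n3; ++z) {
    for (int y = 0; y < n2; ++y) {
      for (int xx = 0; xx < n1; ++xx) {
        int b = 0;
        for (int dz = -r; dz <= r; ++dz) {
          const int zz = reflect_idx(z + dz, n3);
          for (int dy = -r; dy <= r; ++dy) {
            const int yy = reflect_idx(y + dy, n2);
            const R_xlen_t base = (R_xlen_t)(zz * n2 + yy) * n1;
            for (int dx = -r; dx <= r; ++dx) {
              buf[b++] = x[base + reflect_idx(xx + dx, n1)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        out[(R_xlen_t)(z * n2 + y) * n1 + xx] = buf[m / 2];
      }
    }
  }
  return out;
}

// Connected-component labelling of a logical 3D mask.
// connectivity: 6 or 26. Labels are 1..n_components, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_label;
    lab[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % n1;
      const int cy = (cur / n1) % n2;
      const int cz = cur / ((R_xlen_t)n1 * n2);
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = cz + dz;
        if (z2 < 0 || z2 >= n3) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = cy + dy;
          if (y2 < 0 || y2 >= n2) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int x2 = cx + dx;
            if (x2 < 0 || x2 >= n1) continue;
            const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (manh == 0) continue;
            if (connectivity == 6 && manh != 1) continue;
            const R_xlen_t nb = (R_xlen_t)(z2 * n2 + y2) * n1 + x2;
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next_label;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Rigid resampling with trilinear interpolation.
// Physical frame: w = (v - center) * spacing (v 0-based voxel index).
// Forward transform of the moving image: w' = R w + t. The output voxel at w
// samples the input at w_src = R^T (w - t). Out-of-grid samples return `fill`.
// [[Rcpp::export]]
NumericVector resample_rigid_cpp(NumericVector x, IntegerVector dim,
                                 NumericMatrix R, NumericVector t_mm,
                                 NumericVector spacing, NumericVector center,
                                 double fill) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  const double r11 = R(0, 0), r12 = R(0, 1), r13 = R(0, 2);
  const double r21 = R(1, 0), r22 = R(1, 1), r23 = R(1, 2);
  const double r31 = R(2, 0), r32 = R(2, 1), r33 = R(2, 2);
  R_xlen_t o = 0;
  for (int z = 0; z < n3; ++z) {
    const double wz = (z - center[2]) * spacing[2] - t_mm[2];
    for (int y = 0; y < n2; ++y) {
      const double wy = (y - center[1]) * spacing[1] - t_mm[1];
      for (int xx = 0; xx < n1; ++xx, ++o) {
        const double wx = (xx - center[0]) * spacing[0] - t_mm[0];
        // R^T (w - t)
        const double sx = r11 * wx + r21 * wy + r31 * wz;
        const double sy = r12 * wx + r22 * wy + r32 * wz;
        const double sz = r13 * wx + r23 * wy + r33 * wz;
        const double vx = sx / spacing[0] + center[0];
        const double vy = sy / spacing[1] + center[1];
        const double vz = sz / spacing[2] + center[2];
        const int ix = (int)std::floor(vx);
        const int iy = (int)std::floor(vy);
        const int iz = (int)std::floor(vz);
        if (ix < 0 || iy < 0 || iz < 0 ||
            ix >= n1 - 1 || iy >= n2 - 1 || iz >= n3 - 1) {
          // allow exact boundary hit
          if (vx >= 0 && vy >= 0 && vz >= 0 &&
              vx <= n1 - 1 && vy <= n2 - 1 && vz <= n3 - 1) {
            const int jx = std::min(ix, n1 - 2), jy = std::min(iy, n2 - 2),
                      jz = std::min(iz, n3 - 2);
            const double fx = vx - jx, fy = vy - jy, fz = vz - jz;
            double acc = 0.0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                  acc += w * x[(R_xlen_t)((jz + dz) * n2 + (jy + dy)) * n1 +
                               (jx + dx)];
                }
            out[o] = acc;
          } else {
            out[o] = fill;
          }
          continue;
        }
        const double fx = vx - ix, fy = vy - iy, fz = vz - iz;
        const R_xlen_t b000 = (R_xlen_t)(iz * n2 + iy) * n1 + ix;
        const R_xlen_t b001 = b000 + (R_xlen_t)n1 * n2;
        const double c00 = x[b000] * (1 - fx) + x[b000 + 1] * fx;
        const double c10 = x[b000 + n1] * (1 - fx) + x[b000 + n1 + 1] * fx;
        const double c01 = x[b001] * (1 - fx) + x[b001 + 1] * fx;
        const double c11 = x[b001 + n1] * (1 - fx) + x[b001 + n1 + 1] * fx;
        const double c0 = c00 * (1 - fy) + c10 * fy;
        const double c1 = c01 * (1 - fy) + c11 * fy;
        out[o] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}
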