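#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Rigid-body transform convention (shared with the R layer):
// parameters p = (rx, ry, rz, tx, ty, tz); rotations in radians applied in
// x, y, z order (R = Rz * Ry * Rx) about the volume centre, translations in
// mm.  Voxel (i,j,k) (0-based) maps to mm coordinate ((i - cx)*vx, ...),
// cx = (nx-1)/2.  Applying the transform to an image means
// I_new(p) = I_old(T^{-1} p); with invert = true the inverse transform is
// applied instead.  Trilinear interpolation, zero outside the grid.

static inline void rot_matrix(const double rx, const double ry, const double rz,
                              double R[3][3]) {
  const double cx = std::cos(rx), sx = std::sin(rx);
  const double cy = std::cos(ry), sy = std::sin(ry);
  const double cz = std::cos(rz), sz = std::sin(rz);
  // Rz * Ry * Rx
  R[0][0] = cz * cy;
  R[0][1] = cz * sy * sx - sz * cx;
  R[0][2] = cz * sy * cx + sz * sx;
  R[1][0] = sz * cy;
  R[1][1] = sz * sy * sx + cz * cx;
  R[1][2] = sz * sy * cx - cz * sx;
  R[2][0] = -sy;
  R[2][1] = cy * sx;
  R[2][2] = cy * cx;
}

// [[Rcpp::export(name = ".rigidResampleCpp")]]
NumericVector rigid_resample_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector par, NumericVector voxsize,
                                 bool invert) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double vx = voxsize[0], vy = voxsize[1], vz = voxsize[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;

  double R[3][3];
  rot_matrix(par[0], par[1], par[2], R);
  const double tx = par[3], ty = par[4], tz = par[5];

  NumericVector out(vol.size());
  const double *v = vol.begin();
  double *o = out.begin();

  for (int k = 0; k < nz; ++k) {
    const double zmm = (k - cz) * vz;
    for (int j = 0; j < ny; ++j) {
      const double ymm = (j - cy) * vy;
      for (int i = 0; i < nx; ++i) {
        const double xmm = (i - cx) * vx;
        double qx, qy, qz;
        if (!invert) {
          // source = R^T (p - t)
          const double px = xmm - tx, py = ymm - ty, pz = zmm - tz;
          qx = R[0][0] * px + R[1][0] * py + R[2][0] * pz;
          qy = R[0][1] * px + R[1][1] * py + R[2][1] * pz;
          qz = R[0][2] * px + R[1][2] * py + R[2][2] * pz;
        } else {
          // source = R p + t
          qx = R[0][0] * xmm + R[0][1] * ymm + R[0][2] * zmm + tx;
          qy = R[1][0] * xmm + R[1][1] * ymm + R[1][2] * zmm + ty;
          qz = R[2][0] * xmm + R[2][1] * ymm + R[2][2] * zmm + tz;
        }
        // back to (fractional) voxel indices
        const double fi = qx / vx + cx;
        const double fj = qy / vy + cy;
        const double fk = qz / vz + cz;
        const int i0 = (int)std::floor(fi);
        const int j0 = (int)std::floor(fj);
        const int k0 = (int)std::floor(fk);
        double val = 0.0;
        if (i0 >= -1 && i0 < nx && j0 >= -1 && j0 < ny && k0 >= -1 && k0 < nz) {
          const double di = fi - i0, dj = fj - j0, dk = fk - k0;
          for (int dk2 = 0; dk2 <= 1; ++dk2) {
            const int kk = k0 + dk2;
            if (kk < 0 || kk >= nz) continue;
            const double wz = dk2 ? dk : 1.0 - dk;
            for (int dj2 = 0; dj2 <= 1; ++dj2) {
              const int jj = j0 + dj2;
              if (jj < 0 || jj >= ny) continue;
              const double wy = dj2 ? dj : 1.0 - dj;
              for (int di2 = 0; di2 <= 1; ++di2) {
                const int ii = i0 + di2;
                if (ii < 0 || ii >= nx) continue;
                const double wx = di2 ? di : 1.0 - di;
                val += wx * wy * wz *
                       v[ii + (size_t)nx * (jj + (size_t)ny * kk)];
              }
            }
          }
        }
        o[i + (size_t)nx * (j + (size_t)ny * k)] = val;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labeling of a binary 3-D mask; labels are 1..L in
// first-encounter order.
// [[Rcpp::export(name = ".labelComponentsCpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const size_t cur = q.front();
      q.pop();
      const int i = cur % nx;
      const int j = (cur / nx) % ny;
      const int k = cur / ((size_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const size_t t = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[t] && !lab[t]) {
          lab[t] = next;
          q.push(t);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
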