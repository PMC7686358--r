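#include <Rcpp.h>
using namespace Rcpp;

// Counting kernels for the gray-level texture matrices. Arrays are
// flattened (z, y, x) with level 0 marking out-of-mask voxels; `offsets`
// holds one (dz, dy, dx) direction per row.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerVector lev, IntegerVector dims,
                              IntegerMatrix offsets, int ng) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericMatrix m(ng, ng);
  for (int r = 0; r < offsets.nrow(); ++r) {
    const int dz = offsets(r, 0), dy = offsets(r, 1), dx = offsets(r, 2);
    for (int x = std::max(0, -dx); x < std::min(nx, nx - dx); ++x)
      for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y)
        for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z) {
          const int a = lev[idx3(z, y, x, nz, ny)];
          if (a == 0) continue;
          const int b = lev[idx3(z + dz, y + dy, x + dx, nz, ny)];
          if (b == 0) continue;
          m(a - 1, b - 1) += 1.0;
          m(b - 1, a - 1) += 1.0;  // symmetric accumulation
        }
  }
  return m;
}

// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
NumericMatrix glrlm_counts_cpp(IntegerVector lev, IntegerVector dims,
                               IntegerMatrix offsets, int ng, int lmax) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericMatrix m(ng, lmax);
  for (int r = 0; r < offsets.nrow(); ++r) {
    const int dz = offsets(r, 0), dy = offsets(r, 1), dx = offsets(r, 2);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          // only start walking at the first voxel of each line
          const int pz = z - dz, py = y - dy, px = x - dx;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz)
            continue;
          int cz = z, cy = y, cx = x;
          int cur = 0, len = 0;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny &&
                 cz >= 0 && cz < nz) {
            const int g = lev[idx3(cz, cy, cx, nz, ny)];
            if (g == cur) {
              ++len;
            } else {
              if (cur > 0) m(cur - 1, len - 1) += 1.0;
              cur = g;
              len = 1;
            }
            cz += dz; cy += dy; cx += dx;
          }
          if (cur > 0) m(cur - 1, len - 1) += 1.0;
        }
  }
  return m;
}

// per-level difference sums s_i and counts n_i of the NGTDM
// [[Rcpp::export(name = ".ngtdm_counts_cpp")]]
List ngtdm_counts_cpp(IntegerVector lev, IntegerVector dims, int ng) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector s(ng);
  IntegerVector n(ng);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const int g = lev[idx3(z, y, x, nz, ny)];
        if (g == 0) continue;
        double acc = 0.0;
        int cnt = 0;
        for (int dx = -1; dx <= 1; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              const int h = lev[idx3(zz, yy, xx, nz, ny)];
              if (h > 0) { acc += h; ++cnt; }
            }
          }
        }
        if (cnt > 0) {
          s[g - 1] += std::fabs(g - acc / cnt);
          n[g - 1] += 1;
        }
      }
  return List::create(_["s"] = s, _["n"] = n);
}
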