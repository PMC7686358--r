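#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label 26-connected components of equal gray level among in-mask voxels.
// `lev` is a flattened (z, y, x) integer array with 0 marking out-of-mask
// voxels. Returns an integer array of zone ids (0 outside the mask).
// [[Rcpp::export(name = ".label_zones_cpp")]]
IntegerVector label_zones_cpp(IntegerVector lev, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector zone(n, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  int next_id = 0;
  for (int start = 0; start < n; ++start) {
    if (lev[start] == 0 || zone[start] != 0) continue;
    const int g = lev[start];
    ++next_id;
    zone[start] = next_id;
    stack.push_back(start);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int x = v / (nz * ny);
      const int rem = v % (nz * ny);
      const int y = rem / nz;
      const int z = rem % nz;
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
            const int w = zz + nz * (yy + ny * xx);
            if (lev[w] == g && zone[w] == 0) {
              zone[w] = next_id;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  zone.attr("dim") = dims;
  return zone;
}
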