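// Texture-matrix accumulators. Levels are 1..B inside the ROI and 0 outside;
// co-occurrence / run / dependence / grey-tone-difference statistics are
// accumulated in-plane (per axial slice) and summed over slices, the size-zone
// matrix alone is 3D (26-connected), being direction-free.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int at(const IntegerVector& lv, int nx, int ny,
                     int x, int y, int z) {
  return lv[x + nx * (y + ny * z)];
}

// [[Rcpp::export]]
IntegerMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int b,
                       int dx, int dy) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix counts(b, b);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l1 = at(levels, nx, ny, x, y, z);
        if (l1 == 0) continue;
        const int x2 = x + dx, y2 = y + dy;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny) continue;
        const int l2 = at(levels, nx, ny, x2, y2, z);
        if (l2 == 0) continue;
        counts(l1 - 1, l2 - 1) += 1;  // symmetric accumulation
        counts(l2 - 1, l1 - 1) += 1;
      }
  return counts;
}

// [[Rcpp::export]]
IntegerMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int b,
                        int dx, int dy) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxlen = std::max(nx, ny);
  IntegerMatrix counts(b, maxlen);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // start of a line: no predecessor inside the grid
        const int xp = x - dx, yp = y - dy;
        if (xp >= 0 && xp < nx && yp >= 0 && yp < ny) continue;
        int cx = x, cy = y, cur = 0, len = 0;
        while (cx >= 0 && cx < nx && cy >= 0 && cy < ny) {
          const int l = at(levels, nx, ny, cx, cy, z);
          if (l == cur) {
            if (l != 0) ++len;
          } else {
            if (cur != 0) counts(cur - 1, len - 1) += 1;
            cur = l;
            len = (l != 0) ? 1 : 0;
          }
          cx += dx; cy += dy;
        }
        if (cur != 0) counts(cur - 1, len - 1) += 1;
      }
  return counts;
}

// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  std::vector<int> stack;
  int max_size = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seen[i] || levels[i] == 0) continue;
    const int lev = levels[i];
    int size = 0;
    stack.push_back((int)i);
    seen[i] = 1;
    while (!stack.empty()) {
      const int j = stack.back();
      stack.pop_back();
      ++size;
      const int z = j / (nx * ny), r = j % (nx * ny);
      const int y = r / nx, x = r % nx;
      for (int ddz = -1; ddz <= 1; ++ddz)
        for (int ddy = -1; ddy <= 1; ++ddy)
          for (int ddx = -1; ddx <= 1; ++ddx) {
            if (ddx == 0 && ddy == 0 && ddz == 0) continue;
            const int x2 = x + ddx, y2 = y + ddy, z2 = z + ddz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                z2 < 0 || z2 >= nz) continue;
            const int k = x2 + nx * (y2 + ny * z2);
            if (!seen[k] && levels[k] == lev) {
              seen[k] = 1;
              stack.push_back(k);
            }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > max_size) max_size = size;
  }
  IntegerMatrix counts(b, std::max(max_size, 1));
  for (size_t k = 0; k < zones.size(); ++k)
    counts(zones[k].first - 1, zones[k].second - 1) += 1;
  return counts;
}

// [[Rcpp::export]]
IntegerMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int b,
                       int kernel, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int side = 2 * kernel + 1;
  IntegerMatrix counts(b, side * side);  // dependence 0 .. side^2 - 1
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = at(levels, nx, ny, x, y, z);
        if (l == 0) continue;
        int dep = 0;
        for (int ddy = -kernel; ddy <= kernel; ++ddy)
          for (int ddx = -kernel; ddx <= kernel; ++ddx) {
            if (ddx == 0 && ddy == 0) continue;
            const int x2 = x + ddx, y2 = y + ddy;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny) continue;
            const int l2 = at(levels, nx, ny, x2, y2, z);
            if (l2 != 0 && std::abs(l2 - l) <= alpha) ++dep;
          }
        counts(l - 1, dep) += 1;
      }
  return counts;
}

// Returns a B x 2 matrix: column 0 the occurrence counts n_i, column 1 the
// summed absolute deviations s_i from the in-kernel neighbourhood mean.
// Voxels with no in-ROI neighbour inside the kernel are excluded.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int b,
                        int kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(b, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = at(levels, nx, ny, x, y, z);
        if (l == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int ddy = -kernel; ddy <= kernel; ++ddy)
          for (int ddx = -kernel; ddx <= kernel; ++ddx) {
            if (ddx == 0 && ddy == 0) continue;
            const int x2 = x + ddx, y2 = y + ddy;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny) continue;
            const int l2 = at(levels, nx, ny, x2, y2, z);
            if (l2 != 0) { sum += l2; ++cnt; }
          }
        if (cnt > 0) {
          out(l - 1, 0) += 1.0;
          out(l - 1, 1) += std::fabs((double)l - sum / cnt);
        }
      }
  return out;
}
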