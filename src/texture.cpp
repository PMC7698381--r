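#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Index helper for column-major 3D arrays.
static inline int vox(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Per-voxel Haralick maps over a sliding patch.
//
// disc: discretized levels 1..nlevels (column-major, dims nx*ny*nz)
// mask: same grid, nonzero = lesion voxel
// hx, hy, hz: patch half-sizes (patch is (2hx+1) x (2hy+1) x (2hz+1))
// offsets: n_off x 3 integer matrix of co-occurrence displacements
//
// For every mask voxel a GLCM is accumulated from ordered voxel pairs
// (p, p+offset) with BOTH endpoints inside the patch, the grid and the
// mask; each pair is counted in both (a,b) and (b,a) (symmetric GLCM),
// the matrix is normalized to sum 1 and the four statistics computed.
// Zero valid pairs: degenerate convention energy=1, entropy=0,
// homogeneity=1, contrast=0. Entropy is log base 2 with 0*log0 = 0.
// [[Rcpp::export]]
List haralick_maps_cpp(IntegerVector disc, IntegerVector mask, IntegerVector dims,
                       int hx, int hy, int hz, IntegerMatrix offsets, int nlevels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int noff = offsets.nrow();
  NumericVector energy(n, NA_REAL), entropy(n, NA_REAL),
      homogeneity(n, NA_REAL), contrast(n, NA_REAL);
  std::vector<double> glcm((size_t)nlevels * nlevels);

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int c = vox(x, y, z, nx, ny);
        if (!mask[c]) continue;
        std::fill(glcm.begin(), glcm.end(), 0.0);
        double total = 0.0;
        const int x0 = std::max(0, x - hx), x1 = std::min(nx - 1, x + hx);
        const int y0 = std::max(0, y - hy), y1 = std::min(ny - 1, y + hy);
        const int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
        for (int pz = z0; pz <= z1; ++pz) {
          for (int py = y0; py <= y1; ++py) {
            for (int px = x0; px <= x1; ++px) {
              const int p = vox(px, py, pz, nx, ny);
              if (!mask[p]) continue;
              const int a = disc[p] - 1;
              for (int o = 0; o < noff; ++o) {
                const int qx = px + offsets(o, 0);
                const int qy = py + offsets(o, 1);
                const int qz = pz + offsets(o, 2);
                if (qx < x0 || qx > x1 || qy < y0 || qy > y1 ||
                    qz < z0 || qz > z1) continue;
                const int q = vox(qx, qy, qz, nx, ny);
                if (!mask[q]) continue;
                const int b = disc[q] - 1;
                glcm[(size_t)a * nlevels + b] += 1.0;
                glcm[(size_t)b * nlevels + a] += 1.0;
                total += 2.0;
              }
            }
          }
        }
        double en, ent, hom, con;
        if (total <= 0.0) {
          en = 1.0; ent = 0.0; hom = 1.0; con = 0.0;
        } else {
          en = ent = hom = con = 0.0;
          for (int i = 0; i < nlevels; ++i) {
            for (int j = 0; j < nlevels; ++j) {
              const double pij = glcm[(size_t)i * nlevels + j] / total;
              if (pij <= 0.0) continue;
              en += pij * pij;
              ent -= pij * std::log2(pij);
              hom += pij / (1.0 + std::abs(i - j));
              con += pij * (double)(i - j) * (i - j);
            }
          }
        }
        energy[c] = en; entropy[c] = ent; homogeneity[c] = hom; contrast[c] = con;
      }
    }
  }
  return List::create(_["energy"] = energy, _["entropy"] = entropy,
                      _["homogeneity"] = homogeneity, _["contrast"] = contrast);
}

// Whole-mask symmetric GLCM counts pooled over the supplied offsets.
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerVector disc, IntegerVector mask,
                              IntegerVector dims, IntegerMatrix offsets,
                              int nlevels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int noff = offsets.nrow();
  NumericMatrix glcm(nlevels, nlevels);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int p = vox(x, y, z, nx, ny);
        if (!mask[p]) continue;
        const int a = disc[p] - 1;
        for (int o = 0; o < noff; ++o) {
          const int qx = x + offsets(o, 0);
          const int qy = y + offsets(o, 1);
          const int qz = z + offsets(o, 2);
          if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
            continue;
          const int q = vox(qx, qy, qz, nx, ny);
          if (!mask[q]) continue;
          const int b = disc[q] - 1;
          glcm(a, b) += 1.0;
          glcm(b, a) += 1.0;
        }
      }
  return glcm;
}

// Gray level run length counts pooled over directions.
// A run is a maximal streak of equal-level in-mask voxels along a direction.
// Returns nlevels x maxrun counts.
// [[Rcpp::export]]
NumericMatrix glrlm_counts_cpp(IntegerVector disc, IntegerVector mask,
                               IntegerVector dims, IntegerMatrix dirs,
                               int nlevels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxdim = std::max(nx, std::max(ny, nz));
  // runs cannot exceed the grid diagonal in voxel steps
  const int maxrun = 3 * maxdim + 1;
  NumericMatrix rlm(nlevels, maxrun);
  auto inb = [&](int x, int y, int z) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  };
  for (int d = 0; d < dirs.nrow(); ++d) {
    const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int p = vox(x, y, z, nx, ny);
          if (!mask[p]) continue;
          const int g = disc[p];
          // run starts here iff predecessor is absent or differs
          const int bx = x - dx, by = y - dy, bz = z - dz;
          if (inb(bx, by, bz)) {
            const int b = vox(bx, by, bz, nx, ny);
            if (mask[b] && disc[b] == g) continue;
          }
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (inb(cx, cy, cz)) {
            const int q = vox(cx, cy, cz, nx, ny);
            if (!mask[q] || disc[q] != g) break;
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxrun) len = maxrun;
          rlm(g - 1, len - 1) += 1.0;
        }
  }
  return rlm;
}

// Gray level size zones: connected components (26-connectivity) of equal
// level within the mask. Returns a two-column matrix (level, zone size).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector disc, IntegerVector mask,
                              IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlevel, zsize, stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int p = vox(x, y, z, nx, ny);
        if (!mask[p] || seen[p]) continue;
        const int g = disc[p];
        int size = 0;
        stack.clear();
        stack.push_back(p);
        seen[p] = 1;
        while (!stack.empty()) {
          const int c = stack.back(); stack.pop_back();
          ++size;
          const int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                const int qx = cx + dx, qy = cy + dy, qz = cz + dz;
                if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                    qz < 0 || qz >= nz) continue;
                const int q = vox(qx, qy, qz, nx, ny);
                if (!mask[q] || seen[q] || disc[q] != g) continue;
                seen[q] = 1;
                stack.push_back(q);
              }
        }
        zlevel.push_back(g);
        zsize.push_back(size);
      }
  IntegerMatrix out(zlevel.size(), 2);
  for (size_t i = 0; i < zlevel.size(); ++i) {
    out(i, 0) = zlevel[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// Neighborhood gray tone difference accumulators: for each in-mask voxel
// with >= 1 in-mask 26-neighbor, the absolute difference between its level
// and the mean level of those neighbors contributes to s[g]; n[g] counts
// contributing voxels of level g. Returns nlevels x 2 (n_g, s_g).
// [[Rcpp::export]]
NumericMatrix ngtdm_counts_cpp(IntegerVector disc, IntegerVector mask,
                               IntegerVector dims, int nlevels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nlevels, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int p = vox(x, y, z, nx, ny);
        if (!mask[p]) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int qx = x + dx, qy = y + dy, qz = z + dz;
              if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                  qz < 0 || qz >= nz) continue;
              const int q = vox(qx, qy, qz, nx, ny);
              if (!mask[q]) continue;
              sum += disc[q]; ++cnt;
            }
        if (cnt == 0) continue;
        const int g = disc[p] - 1;
        out(g, 0) += 1.0;
        out(g, 1) += std::abs((double)disc[p] - sum / cnt);
      }
  return out;
}

// Neighboring gray level dependence counts with coarseness tolerance
// alpha: dependence count of a voxel = 1 + number of in-mask 26-neighbors
// whose level differs by <= alpha (the center counts itself, so j >= 1).
// Returns nlevels x 27 counts s(g, j).
// [[Rcpp::export]]
NumericMatrix ngldm_counts_cpp(IntegerVector disc, IntegerVector mask,
                               IntegerVector dims, int nlevels, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nlevels, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int p = vox(x, y, z, nx, ny);
        if (!mask[p]) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int qx = x + dx, qy = y + dy, qz = z + dz;
              if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                  qz < 0 || qz >= nz) continue;
              const int q = vox(qx, qy, qz, nx, ny);
              if (!mask[q]) continue;
              if (std::abs(disc[q] - disc[p]) <= alpha) ++dep;
            }
        out(disc[p] - 1, dep - 1) += 1.0;
      }
  return out;
}

// Slice-wise 2D cross-correlation with replicate border padding; the kernel
// is applied independently to every z slice.
// [[Rcpp::export]]
NumericVector conv2d_stack_cpp(NumericVector vol, IntegerVector dims,
                               NumericMatrix kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kx = kernel.nrow(), ky = kernel.ncol();
  const int hx = kx / 2, hy = ky / 2;
  NumericVector out(nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int j = 0; j < ky; ++j) {
          int yy = y + j - hy;
          if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
          for (int i = 0; i < kx; ++i) {
            int xx = x + i - hx;
            if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
            acc += kernel(i, j) * vol[vox(xx, yy, z, nx, ny)];
          }
        }
        out[vox(x, y, z, nx, ny)] = acc;
      }
  return out;
}
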