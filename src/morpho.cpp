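// Voxel morphology kernels: exact Euclidean distance transform,
// sphere-fitting local thickness, connected-component labeling and
// topology-preserving 3D thinning. All volumes are passed as flat
// vectors in R's column-major order with dims = (nx, ny, nz).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double INF = 1e20;

// 1D squared distance transform, lower envelope of parabolas
// (Felzenszwalb & Huttenlocher). f: input costs, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from each TRUE voxel to the
// nearest FALSE voxel. FALSE voxels get 0. Voxels outside the volume are
// treated as no closer than anything inside (i.e. ignored).
// [[Rcpp::export]]
NumericVector edtSquaredCpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d((size_t)n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
      for (int i = 0; i < nx; i++) f[i] = d[base + i];
      dt1d(f, out, nx, v, z);
      for (int i = 0; i < nx; i++) d[base + i] = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)k * nx * ny;
      for (int j = 0; j < ny; j++) f[j] = d[base + (R_xlen_t)j * nx];
      dt1d(f, out, ny, v, z);
      for (int j = 0; j < ny; j++) d[base + (R_xlen_t)j * nx] = out[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)j * nx;
      for (int k = 0; k < nz; k++) f[k] = d[base + (R_xlen_t)k * nx * ny];
      dt1d(f, out, nz, v, z);
      for (int k = 0; k < nz; k++) d[base + (R_xlen_t)k * nx * ny] = out[k];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; i++) res[i] = d[i];
  return res;
}

// Sphere-fitting local thickness (Hildebrand-Rueegsegger): for every TRUE
// voxel, the diameter (in voxel units) of the largest inscribed sphere that
// contains it. Sphere radius at a center c is r(c) = dist(c, background) - 1/2
// so an isolated voxel has thickness one voxel. Centers whose sphere is
// contained in a 26-neighbour's sphere are skipped (exact containment test);
// remaining spheres are stamped in decreasing radius order.
// [[Rcpp::export]]
NumericVector localThicknessCpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d2 = edtSquaredCpp(mask, dims);

  std::vector<double> r((size_t)n, 0.0);
  std::vector<R_xlen_t> centers;
  centers.reserve(1024);
  for (R_xlen_t i = 0; i < n; i++)
    if (mask[i]) {
      r[i] = std::sqrt(d2[i]) - 0.5;
      centers.push_back(i);
    }

  // containment prefilter: drop c if some neighbour n has
  // r[n] >= r[c] + |c - n|  (then sphere(c) subset of sphere(n))
  std::vector<R_xlen_t> kept;
  kept.reserve(centers.size());
  for (R_xlen_t c : centers) {
    int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((R_xlen_t)nx * ny));
    bool contained = false;
    for (int dz = -1; dz <= 1 && !contained; dz++)
      for (int dy = -1; dy <= 1 && !contained; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          R_xlen_t q = X + (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny;
          if (!mask[q]) continue;
          double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          if (r[q] >= r[c] + dist - 1e-12) { contained = true; break; }
        }
    if (!contained) kept.push_back(c);
  }

  std::sort(kept.begin(), kept.end(), [&](R_xlen_t a, R_xlen_t b) {
    return r[a] > r[b];
  });

  NumericVector th(n, 0.0);
  for (R_xlen_t c : kept) {
    double rc = r[c];
    double rc2 = rc * rc + 1e-9;
    int ri = (int)std::floor(rc);
    int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((R_xlen_t)nx * ny));
    double diam = 2.0 * rc;
    for (int dz = -ri; dz <= ri; dz++) {
      int Z = z + dz;
      if (Z < 0 || Z >= nz) continue;
      for (int dy = -ri; dy <= ri; dy++) {
        int Y = y + dy;
        if (Y < 0 || Y >= ny) continue;
        double rem = rc2 - dz * dz - dy * dy;
        if (rem < 0) continue;
        int rx = (int)std::floor(std::sqrt(rem));
        int x0 = std::max(0, x - rx), x1 = std::min(nx - 1, x + rx);
        R_xlen_t base = (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny;
        for (int X = x0; X <= x1; X++) {
          R_xlen_t q = base + X;
          if (mask[q] && th[q] < diam) th[q] = diam;
        }
      }
    }
    if (th[c] < diam) th[c] = diam;  // rc < 0.5 stamps nothing
  }
  // every bone voxel is covered by at least its own sphere
  for (R_xlen_t c : centers)
    if (th[c] <= 0.0) th[c] = 2.0 * r[c];
  return th;
}

// Connected-component labeling (connectivity 6 or 26), BFS in linear-index
// scan order so labels are assigned deterministically (component 1 contains
// the lowest linear index among unlabeled voxels, etc.).
// [[Rcpp::export]]
IntegerVector labelComponentsCpp(LogicalVector mask, IntegerVector dims,
                                 int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int cur = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    lab[s] = cur;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t p = queue[head++];
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (auto& o : offs) {
        int X = x + o[0], Y = y + o[1], Z = z + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t q = X + (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny;
        if (mask[q] && !lab[q]) {
          lab[q] = cur;
          queue.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---- simple-point machinery for thinning --------------------------------

// positions 0..26 in a 3x3x3 block, center = 13
static inline int nbIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected components of the object within N26* (center removed)
static int countC26(const bool nb[27]) {
  bool vis[27] = {false};
  int comp = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || vis[i]) continue;
    comp++;
    int stack[27], top = 0;
    stack[top++] = i;
    vis[i] = true;
    while (top) {
      int p = stack[--top];
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int q = 0; q < 27; q++) {
        if (q == 13 || !nb[q] || vis[q]) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        if (std::abs(px - qx) <= 1 && std::abs(py - qy) <= 1 &&
            std::abs(pz - qz) <= 1) {
          vis[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return comp;
}

// number of 6-connected components of the background restricted to N18
// that contain a face neighbour of the center (Malandain-Bertrand)
static int countC6bar(const bool nb[27]) {
  bool in18[27], bg[27];
  for (int i = 0; i < 27; i++) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (m >= 1 && m <= 2);
    bg[i] = in18[i] && !nb[i];
  }
  bool vis[27] = {false};
  int comp = 0;
  const int faces[6] = {nbIndex(-1, 0, 0), nbIndex(1, 0, 0), nbIndex(0, -1, 0),
                        nbIndex(0, 1, 0),  nbIndex(0, 0, -1), nbIndex(0, 0, 1)};
  for (int fi = 0; fi < 6; fi++) {
    int s = faces[fi];
    if (!bg[s] || vis[s]) continue;
    comp++;
    int stack[27], top = 0;
    stack[top++] = s;
    vis[s] = true;
    while (top) {
      int p = stack[--top];
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int q = 0; q < 27; q++) {
        if (!bg[q] || vis[q]) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        if (std::abs(px - qx) + std::abs(py - qy) + std::abs(pz - qz) == 1) {
          vis[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return comp;
}

static inline void gatherNb(const std::vector<uint8_t>& m, int nx, int ny,
                            int nz, int x, int y, int z, bool nb[27]) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int X = x + dx, Y = y + dy, Z = z + dz;
        bool v = false;
        if (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz)
          v = m[X + (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny] != 0;
        nb[nbIndex(dx, dy, dz)] = v;
      }
}

static inline bool isSimple(const bool nb[27]) {
  return countC26(nb) == 1 && countC6bar(nb) == 1;
}

// endpoint predicates
static inline int nNeighbours26(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; i++)
    if (i != 13 && nb[i]) c++;
  return c;
}
static inline bool isSurfacePoint(const bool nb[27]) {
  // width-1 along some axis: both face neighbours background
  if (!nb[nbIndex(-1, 0, 0)] && !nb[nbIndex(1, 0, 0)]) return true;
  if (!nb[nbIndex(0, -1, 0)] && !nb[nbIndex(0, 1, 0)]) return true;
  if (!nb[nbIndex(0, 0, -1)] && !nb[nbIndex(0, 0, 1)]) return true;
  return false;
}

// Topology-preserving 6-directional thinning to a curve skeleton
// (preserve = 0) or a medial-surface skeleton (preserve = 1). Candidate
// border voxels are collected per direction and deleted sequentially with
// re-verification, which keeps the deletion topology-safe.
// [[Rcpp::export]]
LogicalVector thin3dCpp(LogicalVector mask, IntegerVector dims, int preserve) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> m((size_t)n);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
  bool nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (R_xlen_t p = 0; p < n; p++) {
        if (!m[p]) continue;
        int x = (int)(p % nx), y = (int)((p / nx) % ny),
            z = (int)(p / ((R_xlen_t)nx * ny));
        // quick interior skip: all six face neighbours present
        if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 &&
            z < nz - 1) {
          R_xlen_t sxy = (R_xlen_t)nx * ny;
          if (m[p - 1] && m[p + 1] && m[p - nx] && m[p + nx] &&
              m[p - sxy] && m[p + sxy])
            continue;
        }
        int X = x + dirs[d][0], Y = y + dirs[d][1], Z = z + dirs[d][2];
        // outside the volume counts as background, so volume-spanning
        // structures thin from the faces too; the terminus census excludes
        // border-touching free ends downstream to compensate
        bool borderHere =
            !(X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz) ||
            !m[X + (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny];
        if (!borderHere) continue;
        gatherNb(m, nx, ny, nz, x, y, z, nb);
        if (preserve == 0) {
          if (nNeighbours26(nb) <= 1) continue;
        } else {
          if (isSurfacePoint(nb)) continue;
        }
        if (isSimple(nb)) cand.push_back(p);
      }
      for (R_xlen_t p : cand) {
        int x = (int)(p % nx), y = (int)((p / nx) % ny),
            z = (int)(p / ((R_xlen_t)nx * ny));
        gatherNb(m, nx, ny, nz, x, y, z, nb);
        bool keep;
        if (preserve == 0)
          keep = nNeighbours26(nb) <= 1;
        else
          keep = isSurfacePoint(nb);
        if (!keep && isSimple(nb)) {
          m[p] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}
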