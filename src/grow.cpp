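// Homogeneity-threshold region growing. Growth proceeds in synchronous
// sweeps: at each sweep every frontier voxel (6-adjacent to the region) is
// tested against the running region mean, all admissible voxels join at
// once, and the mean is updated. Sweep-synchronous acceptance makes the
// result independent of voxel enumeration order and the fixed point is
// idempotent: regrowing from the result adds nothing.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector regionGrowCpp(NumericVector vol, LogicalVector seeds,
                            double threshold, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;

  // state: 0 untouched, 1 in frontier, 2 in region
  std::vector<uint8_t> state((size_t)n, 0);
  std::vector<R_xlen_t> frontier, next, accepted;
  double sum = 0.0;
  R_xlen_t count = 0;

  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  for (R_xlen_t i = 0; i < n; i++)
    if (seeds[i]) {
      state[i] = 2;
      sum += vol[i];
      count++;
    }
  if (count == 0) stop("empty seed set");

  // initial frontier: 6-neighbours of the region
  for (R_xlen_t p = 0; p < n; p++) {
    if (state[p] != 2) continue;
    int x = (int)(p % nx), y = (int)((p / nx) % ny),
        z = (int)(p / ((R_xlen_t)nx * ny));
    for (int d = 0; d < 6; d++) {
      int X = x + dx[d], Y = y + dy[d], Z = z + dz[d];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      R_xlen_t q = X + (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny;
      if (state[q] == 0) {
        state[q] = 1;
        frontier.push_back(q);
      }
    }
  }

  while (!frontier.empty()) {
    double mean = sum / count;
    accepted.clear();
    next.clear();
    for (R_xlen_t q : frontier) {
      if (std::abs(vol[q] - mean) <= threshold)
        accepted.push_back(q);
      else
        next.push_back(q);  // may qualify later as the mean drifts
    }
    if (accepted.empty()) break;
    for (R_xlen_t q : accepted) {
      state[q] = 2;
      sum += vol[q];
      count++;
    }
    for (R_xlen_t q : accepted) {
      int x = (int)(q % nx), y = (int)((q / nx) % ny),
          z = (int)(q / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; d++) {
        int X = x + dx[d], Y = y + dy[d], Z = z + dz[d];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t r = X + (R_xlen_t)Y * nx + (R_xlen_t)Z * nx * ny;
        if (state[r] == 0) {
          state[r] = 1;
          next.push_back(r);
        }
      }
    }
    frontier.swap(next);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = state[i] == 2;
  return out;
}
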