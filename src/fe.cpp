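// Sparse assembly for the voxel micro-FE model. Every element shares the
// same 24x24 stiffness (identical cube elements), so assembly reduces to
// scattering one matrix over the element connectivity. Kinematic uniform
// boundary conditions enter through the fixed-dof displacement matrix: the
// routine returns the free-free block (upper triangle, triplet form) and
// the load vectors  f = -K_fb u_b  for all load cases at once.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List feAssembleCpp(IntegerMatrix elemNodes,   // ne x 8, 0-based node ids
                   NumericMatrix Ke,          // 24 x 24 element stiffness
                   IntegerVector freeIndex,   // 3*nnodes; >=0 free dof id, -1 fixed
                   NumericMatrix ubFixed) {   // 3*nnodes x ncase prescribed u
  int ne = elemNodes.nrow();
  int ncase = ubFixed.ncol();
  int nfree = 0;
  for (int i = 0; i < freeIndex.size(); i++)
    if (freeIndex[i] >= 0 && freeIndex[i] + 1 > nfree) nfree = freeIndex[i] + 1;

  std::vector<int> ti, tj;
  std::vector<double> tv;
  // heuristic reservation: ~300 upper-triangle entries per element
  ti.reserve((size_t)ne * 300);
  tj.reserve((size_t)ne * 300);
  tv.reserve((size_t)ne * 300);
  NumericMatrix rhs(nfree, ncase);

  int gdof[24];
  for (int e = 0; e < ne; e++) {
    for (int k = 0; k < 8; k++) {
      int node = elemNodes(e, k);
      gdof[3 * k] = 3 * node;
      gdof[3 * k + 1] = 3 * node + 1;
      gdof[3 * k + 2] = 3 * node + 2;
    }
    for (int a = 0; a < 24; a++) {
      int ga = gdof[a];
      int fa = freeIndex[ga];
      if (fa < 0) continue;
      for (int b = 0; b < 24; b++) {
        int gb = gdof[b];
        int fb = freeIndex[gb];
        double kab = Ke(a, b);
        if (kab == 0.0) continue;
        if (fb >= 0) {
          if (fa <= fb) {  // upper triangle of symmetric K_ff
            ti.push_back(fa);
            tj.push_back(fb);
            tv.push_back(kab);
          }
        } else {
          for (int c = 0; c < ncase; c++) rhs(fa, c) -= kab * ubFixed(gb, c);
        }
      }
    }
  }

  return List::create(Named("i") = wrap(ti), Named("j") = wrap(tj),
                      Named("x") = wrap(tv), Named("rhs") = rhs,
                      Named("nfree") = nfree);
}
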