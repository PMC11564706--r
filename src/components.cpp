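#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a binary mask.
// Components are numbered 1,2,... in order of their first voxel in R's
// column-major (i fastest) scan, so ids are deterministic.
// connectivity: 6 (face), 18 (face+edge) or 26 (face+edge+corner).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const R_xlen_t n = (R_xlen_t)ni * nj * nk;
  IntegerVector lab(n, 0);

  // neighbour offsets for the requested structure element
  std::vector<int> di, dj, dk;
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        di.push_back(x); dj.push_back(y); dk.push_back(z);
      }
  const int nnb = (int)di.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % ni);
      int j = (int)((v / ni) % nj);
      int k = (int)(v / ((R_xlen_t)ni * nj));
      for (int t = 0; t < nnb; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk) continue;
        R_xlen_t w = ii + (R_xlen_t)ni * (jj + (R_xlen_t)nj * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
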