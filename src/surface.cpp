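#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Exact triangulated boundary surface of a binary sample grid.
//
// The input is interpreted as point samples at voxel centers: sample (i,j,k)
// sits at origin + (i + 0.5) * spacing (0-based). A dual-lattice cell is
// solid when all eight of its corner samples are inside; the returned mesh is
// the boundary of the union of solid cells, with vertices exactly at sample
// positions and outward-wound triangles. Applied to a half-voxel corner-
// shifted tumor mask this reproduces the tumor's voxel-corner envelope
// exactly (its enclosed volume equals the voxel volume).
// [[Rcpp::export]]
List voxel_surface_cpp(LogicalVector samples, IntegerVector dim,
                       NumericVector spacing, NumericVector origin) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  if (ni < 2 || nj < 2 || nk < 2)
    stop("sample grid must be at least 2 in every dimension");
  const int ci = ni - 1, cj = nj - 1, ck = nk - 1;

  auto sid = [&](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)ni * (j + (R_xlen_t)nj * k);
  };
  // solid cells: all 8 corner samples inside
  std::vector<char> solid((R_xlen_t)ci * cj * ck, 0);
  auto cid = [&](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)ci * (j + (R_xlen_t)cj * k);
  };
  for (int k = 0; k < ck; ++k)
    for (int j = 0; j < cj; ++j)
      for (int i = 0; i < ci; ++i) {
        bool all = true;
        for (int dz = 0; dz < 2 && all; ++dz)
          for (int dy = 0; dy < 2 && all; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              if (!samples[sid(i + dx, j + dy, k + dz)]) { all = false; break; }
        if (all) solid[cid(i, j, k)] = 1;
      }

  // exposed face templates: for each of the 6 directions, the 4 corner
  // offsets (relative to the cell's min sample) in outward CCW order
  static const int faceCorner[6][4][3] = {
    // -x
    {{0,0,0},{0,0,1},{0,1,1},{0,1,0}},
    // +x
    {{1,0,0},{1,1,0},{1,1,1},{1,0,1}},
    // -y
    {{0,0,0},{1,0,0},{1,0,1},{0,0,1}},
    // +y
    {{0,1,0},{0,1,1},{1,1,1},{1,1,0}},
    // -z
    {{0,0,0},{0,1,0},{1,1,0},{1,0,0}},
    // +z
    {{0,0,1},{1,0,1},{1,1,1},{0,1,1}}
  };
  static const int dirs[6][3] = {
    {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
  };

  std::unordered_map<R_xlen_t, int> vmap; // sample id -> compact vertex index
  std::vector<R_xlen_t> vids;
  std::vector<int> tri; // triples of vertex indices (0-based)

  auto vertexOf = [&](int i, int j, int k) -> int {
    R_xlen_t s = sid(i, j, k);
    auto it = vmap.find(s);
    if (it != vmap.end()) return it->second;
    int idx = (int)vids.size();
    vmap.emplace(s, idx);
    vids.push_back(s);
    return idx;
  };

  for (int k = 0; k < ck; ++k)
    for (int j = 0; j < cj; ++j)
      for (int i = 0; i < ci; ++i) {
        if (!solid[cid(i, j, k)]) continue;
        for (int d = 0; d < 6; ++d) {
          int iN = i + dirs[d][0], jN = j + dirs[d][1], kN = k + dirs[d][2];
          bool open = (iN < 0 || iN >= ci || jN < 0 || jN >= cj ||
                       kN < 0 || kN >= ck) || !solid[cid(iN, jN, kN)];
          if (!open) continue;
          int q[4];
          for (int c = 0; c < 4; ++c)
            q[c] = vertexOf(i + faceCorner[d][c][0],
                            j + faceCorner[d][c][1],
                            k + faceCorner[d][c][2]);
          tri.push_back(q[0]); tri.push_back(q[1]); tri.push_back(q[2]);
          tri.push_back(q[0]); tri.push_back(q[2]); tri.push_back(q[3]);
        }
      }

  const int nV = (int)vids.size();
  const int nF = (int)tri.size() / 3;
  if (nF == 0) stop("no surface: mask has no corner-complete cell");

  NumericMatrix V(nV, 3);
  for (int v = 0; v < nV; ++v) {
    R_xlen_t s = vids[v];
    int i = (int)(s % ni);
    int j = (int)((s / ni) % nj);
    int k = (int)(s / ((R_xlen_t)ni * nj));
    V(v, 0) = origin[0] + (i + 0.5) * spacing[0];
    V(v, 1) = origin[1] + (j + 0.5) * spacing[1];
    V(v, 2) = origin[2] + (k + 0.5) * spacing[2];
  }
  IntegerMatrix F(nF, 3);
  for (int f = 0; f < nF; ++f) {
    F(f, 0) = tri[3 * f] + 1;
    F(f, 1) = tri[3 * f + 1] + 1;
    F(f, 2) = tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
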