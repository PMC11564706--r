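#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Quickhull for 3D point sets with conflict lists.
// Returns triangular facets (1-based indices into the input points, outward
// CCW winding), unit outward facet normals and plane offsets (n . x <= o for
// interior points), the hull vertex indices, and the enclosed volume.

namespace {

struct Face {
  int v[3];
  int nb[3];           // neighbour across edge (v[i], v[(i+1)%3])
  double n[3], off;    // outward plane
  std::vector<int> pts; // conflict points
  bool dead = false;
};

inline void plane(const NumericMatrix& P, Face& f) {
  double ax = P(f.v[0], 0), ay = P(f.v[0], 1), az = P(f.v[0], 2);
  double ux = P(f.v[1], 0) - ax, uy = P(f.v[1], 1) - ay, uz = P(f.v[1], 2) - az;
  double wx = P(f.v[2], 0) - ax, wy = P(f.v[2], 1) - ay, wz = P(f.v[2], 2) - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double len = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (len <= 0) { f.n[0] = f.n[1] = f.n[2] = 0; f.off = 0; return; }
  f.n[0] = nx / len; f.n[1] = ny / len; f.n[2] = nz / len;
  f.off = f.n[0] * ax + f.n[1] * ay + f.n[2] * az;
}

inline double dist(const NumericMatrix& P, const Face& f, int p) {
  return f.n[0] * P(p, 0) + f.n[1] * P(p, 1) + f.n[2] * P(p, 2) - f.off;
}

} // namespace

// [[Rcpp::export]]
List quickhull3d_cpp(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull in 3D needs at least 4 points");

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (P(i, d) < lo[d]) lo[d] = P(i, d);
      if (P(i, d) > hi[d]) hi[d] = P(i, d);
    }
  double diag = 0;
  for (int d = 0; d < 3; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
  diag = std::sqrt(diag);
  if (!(diag > 0)) stop("degenerate point set: zero extent");
  const double eps = 1e-9 * diag;

  // --- initial simplex: two farthest extreme points, then farthest from the
  // line, then farthest from the plane
  int e[6];
  for (int d = 0; d < 3; ++d) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (P(i, d) < P(imin, d)) imin = i;
      if (P(i, d) > P(imax, d)) imax = i;
    }
    e[2 * d] = imin; e[2 * d + 1] = imax;
  }
  int a = 0, b = 0; double best = -1;
  for (int s = 0; s < 6; ++s)
    for (int t = s + 1; t < 6; ++t) {
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = P(e[s], d) - P(e[t], d);
        d2 += dd * dd;
      }
      if (d2 > best) { best = d2; a = e[s]; b = e[t]; }
    }
  if (!(best > eps * eps)) stop("degenerate point set: all points coincide");

  double ab[3];
  for (int d = 0; d < 3; ++d) ab[d] = P(b, d) - P(a, d);
  const double abLen = std::sqrt(ab[0]*ab[0] + ab[1]*ab[1] + ab[2]*ab[2]);
  int c = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double ap[3];
    for (int d = 0; d < 3; ++d) ap[d] = P(i, d) - P(a, d);
    double cx = ab[1] * ap[2] - ab[2] * ap[1];
    double cy = ab[2] * ap[0] - ab[0] * ap[2];
    double cz = ab[0] * ap[1] - ab[1] * ap[0];
    double dl = std::sqrt(cx * cx + cy * cy + cz * cz) / abLen;
    if (dl > best) { best = dl; c = i; }
  }
  if (c < 0) stop("degenerate point set: all points collinear");

  Face f0; f0.v[0] = a; f0.v[1] = b; f0.v[2] = c;
  plane(P, f0);
  int dpt = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d2 = std::fabs(dist(P, f0, i));
    if (d2 > best) { best = d2; dpt = i; }
  }
  if (dpt < 0) stop("degenerate point set: all points coplanar");

  // interior reference point
  double in[3];
  for (int d = 0; d < 3; ++d)
    in[d] = (P(a, d) + P(b, d) + P(c, d) + P(dpt, d)) / 4.0;

  std::vector<Face> faces;
  faces.reserve(256);
  {
    int tv[4] = {a, b, c, dpt};
    int tf[4][3] = {{0,1,2},{0,2,3},{0,3,1},{1,3,2}};
    for (int f = 0; f < 4; ++f) {
      Face fc;
      for (int d = 0; d < 3; ++d) fc.v[d] = tv[tf[f][d]];
      plane(P, fc);
      double side = fc.n[0]*in[0] + fc.n[1]*in[1] + fc.n[2]*in[2] - fc.off;
      if (side > 0) { std::swap(fc.v[1], fc.v[2]); plane(P, fc); }
      faces.push_back(fc);
    }
    // adjacency by shared (undirected) edges
    std::map<std::pair<int,int>, std::pair<int,int>> em;
    for (int f = 0; f < 4; ++f)
      for (int s = 0; s < 3; ++s) {
        int u = faces[f].v[s], w = faces[f].v[(s + 1) % 3];
        auto key = std::make_pair(std::min(u, w), std::max(u, w));
        auto it = em.find(key);
        if (it == em.end()) em[key] = {f, s};
        else {
          faces[f].nb[s] = it->second.first;
          faces[it->second.first].nb[it->second.second] = f;
        }
      }
  }

  // initial conflict lists: assign each point to the facet it is farthest above
  for (int i = 0; i < n; ++i) {
    if (i == a || i == b || i == c || i == dpt) continue;
    int bestf = -1; double bd = eps;
    for (int f = 0; f < 4; ++f) {
      double d2 = dist(P, faces[f], i);
      if (d2 > bd) { bd = d2; bestf = f; }
    }
    if (bestf >= 0) faces[bestf].pts.push_back(i);
  }

  std::vector<int> pending;
  for (int f = 0; f < 4; ++f)
    if (!faces[f].pts.empty()) pending.push_back(f);

  std::vector<int> visible, horizonFace, horizonSide;
  std::vector<char> mark;

  while (!pending.empty()) {
    int f0i = pending.back(); pending.pop_back();
    if (faces[f0i].dead || faces[f0i].pts.empty()) continue;
    // farthest conflict point of this face
    int p = -1; double bd = -1;
    for (int q : faces[f0i].pts) {
      double d2 = dist(P, faces[f0i], q);
      if (d2 > bd) { bd = d2; p = q; }
    }
    if (p < 0 || bd <= eps) { faces[f0i].pts.clear(); continue; }

    // find all facets visible from p (DFS over adjacency)
    visible.clear(); horizonFace.clear(); horizonSide.clear();
    mark.assign(faces.size(), 0);
    std::vector<int> stack;
    stack.push_back(f0i); mark[f0i] = 1;
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      visible.push_back(f);
      for (int s = 0; s < 3; ++s) {
        int g = faces[f].nb[s];
        if (mark[g]) continue;
        if (dist(P, faces[g], p) > eps) { mark[g] = 1; stack.push_back(g); }
        else { horizonFace.push_back(f); horizonSide.push_back(s); }
      }
    }

    // gather orphaned conflict points
    std::vector<int> orphans;
    for (int f : visible) {
      faces[f].dead = true;
      for (int q : faces[f].pts) if (q != p) orphans.push_back(q);
      faces[f].pts.clear();
    }

    // build the new fan: one facet per horizon edge
    std::vector<int> newIdx;
    std::map<std::pair<int,int>, std::pair<int,int>> em;
    for (size_t h = 0; h < horizonFace.size(); ++h) {
      int f = horizonFace[h], s = horizonSide[h];
      int u = faces[f].v[s], w = faces[f].v[(s + 1) % 3];
      int g = faces[f].nb[s]; // live neighbour beyond the horizon
      Face nf;
      nf.v[0] = u; nf.v[1] = w; nf.v[2] = p;
      plane(P, nf);
      double side = nf.n[0]*in[0] + nf.n[1]*in[1] + nf.n[2]*in[2] - nf.off;
      if (side > 0) { std::swap(nf.v[0], nf.v[1]); plane(P, nf); }
      int idx = (int)faces.size();
      faces.push_back(nf);
      newIdx.push_back(idx);
      // stitch to the live neighbour across the horizon edge
      int gs = -1;
      for (int t = 0; t < 3; ++t) {
        int gu = faces[g].v[t], gw = faces[g].v[(t + 1) % 3];
        if ((gu == u && gw == w) || (gu == w && gw == u)) { gs = t; break; }
      }
      if (gs < 0) stop("internal hull error: horizon edge not found");
      int ns = -1;
      for (int t = 0; t < 3; ++t) {
        int nu = faces[idx].v[t], nw = faces[idx].v[(t + 1) % 3];
        if ((nu == u && nw == w) || (nu == w && nw == u)) { ns = t; break; }
      }
      faces[idx].nb[ns] = g;
      faces[g].nb[gs] = idx;
      // remaining two edges (those touching p): match via map
      for (int t = 0; t < 3; ++t) {
        if (t == ns) continue;
        int nu = faces[idx].v[t], nw = faces[idx].v[(t + 1) % 3];
        auto key = std::make_pair(std::min(nu, nw), std::max(nu, nw));
        auto it = em.find(key);
        if (it == em.end()) em[key] = {idx, t};
        else {
          faces[idx].nb[t] = it->second.first;
          faces[it->second.first].nb[it->second.second] = idx;
          em.erase(it);
        }
      }
    }
    if (!em.empty()) stop("internal hull error: open horizon fan");

    // redistribute orphans to the facet they are farthest above
    for (int q : orphans) {
      int bestf = -1; double bq = eps;
      for (int idx : newIdx) {
        double d2 = dist(P, faces[idx], q);
        if (d2 > bq) { bq = d2; bestf = idx; }
      }
      if (bestf >= 0) faces[bestf].pts.push_back(q);
    }
    for (int idx : newIdx)
      if (!faces[idx].pts.empty()) pending.push_back(idx);
  }

  // collect live facets
  std::vector<int> live;
  for (size_t f = 0; f < faces.size(); ++f)
    if (!faces[f].dead) live.push_back((int)f);
  const int nF = (int)live.size();

  IntegerMatrix Fm(nF, 3);
  NumericMatrix Nm(nF, 3);
  NumericVector off(nF);
  double vol = 0;
  std::vector<char> isv(n, 0);
  for (int f = 0; f < nF; ++f) {
    const Face& fc = faces[live[f]];
    for (int d = 0; d < 3; ++d) {
      Fm(f, d) = fc.v[d] + 1;
      Nm(f, d) = fc.n[d];
      isv[fc.v[d]] = 1;
    }
    off[f] = fc.off;
    // signed tetra volume wrt interior point
    double u[3], v[3], w[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = P(fc.v[0], d) - in[d];
      v[d] = P(fc.v[1], d) - in[d];
      w[d] = P(fc.v[2], d) - in[d];
    }
    vol += (u[0] * (v[1] * w[2] - v[2] * w[1]) -
            u[1] * (v[0] * w[2] - v[2] * w[0]) +
            u[2] * (v[0] * w[1] - v[1] * w[0])) / 6.0;
  }
  std::vector<int> hv;
  for (int i = 0; i < n; ++i) if (isv[i]) hv.push_back(i + 1);

  return List::create(_["faces"] = Fm, _["normals"] = Nm, _["offsets"] = off,
                      _["vertexIndices"] = wrap(hv), _["volume"] = vol);
}
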