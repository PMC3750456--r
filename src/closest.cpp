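#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Closest point on a triangle mesh for a set of query points, with signed
// distance via angle-weighted pseudonormals (Baerentzen & Aanaes): the sign
// uses the face normal when the foot point is in a face interior, the sum of
// adjacent face normals on an edge, and the angle-weighted vertex normal at a
// vertex. Triangles are binned into a sparse uniform grid; queries scan cell
// shells of growing Chebyshev radius with an exact distance bound, so results
// equal a full scan. Exact distance ties are broken toward the smallest
// triangle index.

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v{x, y, z}; return v; }
static inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 add(const V3 &a, const V3 &b) { return v3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 scl(const V3 &a, double s) { return v3(a.x*s, a.y*s, a.z*s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
// feature: 0..2 vertex a/b/c, 3..5 edge ab/bc/ca, 6 face interior.
static V3 closest_on_tri(const V3 &p, const V3 &a, const V3 &b, const V3 &c,
                         int &feature) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { feature = 0; return a; }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { feature = 1; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3); feature = 3; return add(a, scl(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { feature = 2; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6); feature = 5; return add(a, scl(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    feature = 4; return add(b, scl(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  feature = 6;
  return add(a, add(scl(ab, v), scl(ac, w)));
}

static inline uint64_t cell_key(int cx, int cy, int cz) {
  return ((uint64_t)(uint32_t)cx << 42) ^ ((uint64_t)(uint32_t)cy << 21) ^ (uint64_t)(uint32_t)cz;
}

// [[Rcpp::export(name = ".closest_point_mesh")]]
List closest_point_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q,
                        double max_dist) {
  const int nv = V.nrow(), nf = F.nrow(), nq = Q.nrow();
  if (nf == 0) stop("mesh has no faces");
  std::vector<V3> vert(nv);
  for (int i = 0; i < nv; ++i) vert[i] = v3(V(i,0), V(i,1), V(i,2));
  std::vector<V3> fnorm(nf);
  std::vector<V3> vnorm(nv, v3(0,0,0));
  std::unordered_map<uint64_t, V3> enorm;
  enorm.reserve(nf * 2);
  auto ekey = [](int a, int b) {
    return (a < b) ? ((uint64_t)a << 32 | (uint32_t)b) : ((uint64_t)b << 32 | (uint32_t)a);
  };
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f,0) - 1, ib = F(f,1) - 1, ic = F(f,2) - 1;
    const V3 &a = vert[ia], &b = vert[ib], &c = vert[ic];
    V3 n = cross(sub(b, a), sub(c, a));
    double l = norm(n);
    fnorm[f] = (l > 0) ? scl(n, 1.0 / l) : v3(0, 0, 0);
    // angle-weighted accumulation at each corner
    const int idx[3] = {ia, ib, ic};
    for (int t = 0; t < 3; ++t) {
      const V3 &p0 = vert[idx[t]], &p1 = vert[idx[(t+1)%3]], &p2 = vert[idx[(t+2)%3]];
      V3 e1 = sub(p1, p0), e2 = sub(p2, p0);
      double l1 = norm(e1), l2 = norm(e2);
      double ang = 0;
      if (l1 > 0 && l2 > 0) {
        double cs = dot(e1, e2) / (l1 * l2);
        if (cs > 1) cs = 1; if (cs < -1) cs = -1;
        ang = std::acos(cs);
      }
      vnorm[idx[t]] = add(vnorm[idx[t]], scl(fnorm[f], ang));
    }
    for (int t = 0; t < 3; ++t) {
      uint64_t k = ekey(idx[t], idx[(t+1)%3]);
      auto it = enorm.find(k);
      if (it == enorm.end()) enorm.emplace(k, fnorm[f]);
      else it->second = add(it->second, fnorm[f]);
    }
  }
  // uniform grid over triangle bounding boxes
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < nv; ++i) {
    const double p[3] = {vert[i].x, vert[i].y, vert[i].z};
    for (int d = 0; d < 3; ++d) { if (p[d] < lo[d]) lo[d] = p[d]; if (p[d] > hi[d]) hi[d] = p[d]; }
  }
  double ext = 0;
  for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
  double h = ext / std::max(1.0, std::cbrt((double)nf));
  if (!(h > 0)) h = 1.0;
  h *= 1.5;
  std::unordered_map<uint64_t, std::vector<int> > grid;
  grid.reserve(nf * 2);
  auto cell_of = [&](double x, int d) { return (int)std::floor((x - lo[d]) / h); };
  for (int f = 0; f < nf; ++f) {
    const V3 *tv[3] = {&vert[F(f,0)-1], &vert[F(f,1)-1], &vert[F(f,2)-1]};
    int cmin[3], cmax[3];
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int t = 0; t < 3; ++t) {
        double x = (d == 0) ? tv[t]->x : (d == 1) ? tv[t]->y : tv[t]->z;
        mn = std::min(mn, x); mx = std::max(mx, x);
      }
      cmin[d] = cell_of(mn, d); cmax[d] = cell_of(mx, d);
    }
    for (int cz = cmin[2]; cz <= cmax[2]; ++cz)
      for (int cy = cmin[1]; cy <= cmax[1]; ++cy)
        for (int cx = cmin[0]; cx <= cmax[0]; ++cx)
          grid[cell_key(cx, cy, cz)].push_back(f);
  }
  int cmaxall[3];
  for (int d = 0; d < 3; ++d) cmaxall[d] = cell_of(hi[d], d);

  NumericVector dist(nq), sdist(nq);
  IntegerVector tri(nq);
  NumericMatrix CP(nq, 3), N(nq, 3);
  std::vector<int> stamp(nf, -1);
  const int rmax = (int)(std::max(ext / h, 1.0)) + 2;
  for (int q = 0; q < nq; ++q) {
    const V3 p = v3(Q(q,0), Q(q,1), Q(q,2));
    // distance from p to its clamped home cell (0 if inside the grid)
    int c0[3] = {cell_of(p.x, 0), cell_of(p.y, 1), cell_of(p.z, 2)};
    double d0sq = 0;
    for (int d = 0; d < 3; ++d) {
      double x = (d == 0) ? p.x : (d == 1) ? p.y : p.z;
      if (c0[d] < 0) { double g = lo[d] - x; d0sq += g * g; c0[d] = 0; }
      else if (c0[d] > cmaxall[d]) {
        double g = x - (lo[d] + (cmaxall[d] + 1) * h); if (g > 0) d0sq += g * g;
        c0[d] = cmaxall[d];
      }
    }
    const double d0 = std::sqrt(d0sq);
    double best = std::numeric_limits<double>::infinity();
    int best_f = -1, best_feat = 6;
    V3 best_cp = v3(0,0,0);
    for (int r = 0; r <= rmax; ++r) {
      if (r > 0 && (double)(r - 1) * h - d0 > std::min(best, max_dist)) break;
      for (int cz = c0[2] - r; cz <= c0[2] + r; ++cz) {
        if (cz < 0 || cz > cmaxall[2]) continue;
        for (int cy = c0[1] - r; cy <= c0[1] + r; ++cy) {
          if (cy < 0 || cy > cmaxall[1]) continue;
          for (int cx = c0[0] - r; cx <= c0[0] + r; ++cx) {
            if (cx < 0 || cx > cmaxall[0]) continue;
            const int cheb = std::max(std::abs(cx - c0[0]),
                             std::max(std::abs(cy - c0[1]), std::abs(cz - c0[2])));
            if (cheb != r) continue;
            auto it = grid.find(cell_key(cx, cy, cz));
            if (it == grid.end()) continue;
            for (int f : it->second) {
              if (stamp[f] == q) continue;
              stamp[f] = q;
              int feat;
              const V3 cp = closest_on_tri(p, vert[F(f,0)-1], vert[F(f,1)-1],
                                           vert[F(f,2)-1], feat);
              const double dd = norm(sub(p, cp));
              if (dd < best - 1e-15 ||
                  (std::fabs(dd - best) <= 1e-15 && f < best_f)) {
                best = dd; best_f = f; best_feat = feat; best_cp = cp;
              }
            }
          }
        }
      }
    }
    if (best_f < 0 || best > max_dist) {
      dist[q] = NA_REAL; sdist[q] = NA_REAL; tri[q] = NA_INTEGER;
      CP(q,0) = NA_REAL; CP(q,1) = NA_REAL; CP(q,2) = NA_REAL;
      N(q,0) = NA_REAL; N(q,1) = NA_REAL; N(q,2) = NA_REAL;
      continue;
    }
    // pseudonormal at the closest feature
    V3 n;
    const int ia = F(best_f,0) - 1, ib = F(best_f,1) - 1, ic = F(best_f,2) - 1;
    if (best_feat == 6) n = fnorm[best_f];
    else if (best_feat <= 2) n = vnorm[best_feat == 0 ? ia : (best_feat == 1 ? ib : ic)];
    else {
      int e0 = (best_feat == 3) ? ia : (best_feat == 4) ? ib : ic;
      int e1 = (best_feat == 3) ? ib : (best_feat == 4) ? ic : ia;
      n = enorm[ekey(e0, e1)];
    }
    double l = norm(n);
    if (l > 0) n = scl(n, 1.0 / l);
    dist[q] = best;
    sdist[q] = (dot(sub(p, best_cp), n) >= 0) ? best : -best;
    tri[q] = best_f + 1;
    CP(q,0) = best_cp.x; CP(q,1) = best_cp.y; CP(q,2) = best_cp.z;
    N(q,0) = n.x; N(q,1) = n.y; N(q,2) = n.z;
  }
  return List::create(_["dist"] = dist, _["signed_dist"] = sdist,
                      _["tri"] = tri, _["point"] = CP, _["normal"] = N);
}
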