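#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra over the voxel-center grid. Each cell between eight
// neighbouring voxel centers is split into six tetrahedra sharing the main
// diagonal (Kuhn subdivision), which is consistent across neighbouring cells,
// so the extracted isosurface is watertight. Iso-vertices are shared through
// a global edge table, triangles are oriented outward (normal pointing from
// values above `level` toward values below it).

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static inline int iso_vertex(MTState &st, uint64_t ga, uint64_t gb,
                             double va, double vb, double level,
                             const double *pa, const double *pb) {
  const uint64_t key = (ga < gb) ? (ga << 32 | gb) : (gb << 32 | ga);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (std::fabs(vb - va) < 1e-300) ? 0.5 : (level - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  const int id = (int)st.vx.size();
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_vertex.emplace(key, id);
  return id;
}

static inline void emit_tri(MTState &st, int a, int b, int c,
                            const double *dir) {
  // orient so the normal has positive dot with dir (inside -> outside)
  const double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  const double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  const double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  if (nx * dir[0] + ny * dir[1] + nz * dir[2] < 0) std::swap(b, c);
  st.tri.push_back(a); st.tri.push_back(b); st.tri.push_back(c);
}

// [[Rcpp::export(name = ".marching_tets")]]
List marching_tets(NumericVector field, IntegerVector dims, double level,
                   NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != field.size()) stop("field does not match dims");
  MTState st;
  // six tetrahedra: axis insertion orders (permutations of x,y,z)
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  double corner_pos[8][3];
  double corner_val[8];
  uint64_t corner_gid[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; ++b) {
          const int ii = i + (b & 1), jj = j + ((b >> 1) & 1), kk = k + ((b >> 2) & 1);
          const R_xlen_t idx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          corner_val[b] = field[idx];
          corner_gid[b] = (uint64_t)idx;
          corner_pos[b][0] = origin[0] + ii * spacing[0];
          corner_pos[b][1] = origin[1] + jj * spacing[1];
          corner_pos[b][2] = origin[2] + kk * spacing[2];
          if (corner_val[b] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int tpi = 0; tpi < 6; ++tpi) {
          int tv[4];
          tv[0] = 0;
          tv[1] = tv[0] | (1 << perms[tpi][0]);
          tv[2] = tv[1] | (1 << perms[tpi][1]);
          tv[3] = 7;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int t = 0; t < 4; ++t) {
            if (corner_val[tv[t]] > level) ins[ni++] = tv[t]; else outs[no++] = tv[t];
          }
          if (ni == 0 || ni == 4) continue;
          double dir[3];  // from inside centroid toward outside centroid
          for (int d = 0; d < 3; ++d) {
            double ci = 0, co = 0;
            for (int t = 0; t < ni; ++t) ci += corner_pos[ins[t]][d];
            for (int t = 0; t < no; ++t) co += corner_pos[outs[t]][d];
            dir[d] = co / no - ci / ni;
          }
          if (ni == 1 || ni == 3) {
            const int a = (ni == 1) ? ins[0] : outs[0];
            const int *others = (ni == 1) ? outs : ins;
            int e[3];
            for (int t = 0; t < 3; ++t)
              e[t] = iso_vertex(st, corner_gid[a], corner_gid[others[t]],
                                corner_val[a], corner_val[others[t]], level,
                                corner_pos[a], corner_pos[others[t]]);
            emit_tri(st, e[0], e[1], e[2], dir);
          } else {  // ni == 2: quad split into two triangles
            const int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            const int eac = iso_vertex(st, corner_gid[a], corner_gid[c], corner_val[a], corner_val[c], level, corner_pos[a], corner_pos[c]);
            const int ead = iso_vertex(st, corner_gid[a], corner_gid[d], corner_val[a], corner_val[d], level, corner_pos[a], corner_pos[d]);
            const int ebd = iso_vertex(st, corner_gid[b], corner_gid[d], corner_val[b], corner_val[d], level, corner_pos[b], corner_pos[d]);
            const int ebc = iso_vertex(st, corner_gid[b], corner_gid[c], corner_val[b], corner_val[c], level, corner_pos[b], corner_pos[c]);
            emit_tri(st, eac, ead, ebd, dir);
            emit_tri(st, eac, ebd, ebc, dir);
          }
        }
      }
    }
  }
  const int nv = (int)st.vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0) = st.vx[v]; V(v,1) = st.vy[v]; V(v,2) = st.vz[v]; }
  const int nf = (int)st.tri.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f,0) = st.tri[3*f] + 1; F(f,1) = st.tri[3*f+1] + 1; F(f,2) = st.tri[3*f+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
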