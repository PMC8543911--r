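#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface by marching tetrahedra on a consistent 6-tet cube decomposition
// (all tets share the v0-v6 cube diagonal, so faces match between cubes and
// the mesh is watertight/manifold for level sets away from the border).

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// cube corner offsets (x, y, z)
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge2vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const double* vol;
  double level;
  int nx, ny, nz;

  int edge_vertex(R_xlen_t ga, R_xlen_t gb, double va, double vb,
                  int ax, int ay, int az, int bx, int by, int bz) {
    uint64_t key = ga < gb ? ((uint64_t)ga << 32 | (uint64_t)gb)
                           : ((uint64_t)gb << 32 | (uint64_t)ga);
    auto it = edge2vid.find(key);
    if (it != edge2vid.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    int vid = (int)vx.size() - 1;
    edge2vid[key] = vid;
    return vid;
  }
};

// [[Rcpp::export(name = ".mtetra_cpp")]]
List mtetra_cpp(NumericVector vol, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MeshAcc m;
  m.vol = REAL(vol); m.level = level; m.nx = nx; m.ny = ny; m.nz = nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double cv[8];
        R_xlen_t gid[8];
        int cx[8], cy[8], cz[8];
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          cx[c] = i + CORNER[c][0]; cy[c] = j + CORNER[c][1]; cz[c] = k + CORNER[c][2];
          gid[c] = cx[c] + sy * cy[c] + sz * cz[c];
          cv[c] = m.vol[gid[c]];
          if (cv[c] > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int above[4], nab = 0;
          for (int c = 0; c < 4; ++c) above[c] = cv[T[c]] > level ? 1 : 0, nab += above[c];
          if (nab == 0 || nab == 4) continue;
          // collect crossing edges in a fixed order
          int ev[4], ne = 0; // vertex ids
          static const int TE[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
          int singles = -1;
          if (nab == 1 || nab == 3) {
            int want = (nab == 1) ? 1 : 0;
            for (int c = 0; c < 4; ++c) if (above[c] == want) singles = c;
            for (int c = 0; c < 4; ++c) {
              if (c == singles) continue;
              int a = T[singles], b = T[c];
              ev[ne++] = m.edge_vertex(gid[a], gid[b], cv[a], cv[b],
                                       cx[a], cy[a], cz[a], cx[b], cy[b], cz[b]);
            }
            m.tri.push_back(ev[0]); m.tri.push_back(ev[1]); m.tri.push_back(ev[2]);
          } else { // 2-2 split -> quad
            // find the two "above" corners
            int A[2], B[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c) (above[c] ? A[na++] : B[nb++]) = c;
            // edges A0-B0, A0-B1, A1-B1, A1-B0 form the quad in order
            int pairs[4][2] = {{A[0],B[0]},{A[0],B[1]},{A[1],B[1]},{A[1],B[0]}};
            for (int e = 0; e < 4; ++e) {
              int a = T[pairs[e][0]], b = T[pairs[e][1]];
              ev[e] = m.edge_vertex(gid[a], gid[b], cv[a], cv[b],
                                    cx[a], cy[a], cz[a], cx[b], cy[b], cz[b]);
            }
            m.tri.push_back(ev[0]); m.tri.push_back(ev[1]); m.tri.push_back(ev[2]);
            m.tri.push_back(ev[0]); m.tri.push_back(ev[2]); m.tri.push_back(ev[3]);
            (void)TE;
          }
        }
      }
  int nv = (int)m.vx.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) { verts(v,0)=m.vx[v]; verts(v,1)=m.vy[v]; verts(v,2)=m.vz[v]; }
  int nt = (int)m.tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) tris(t, c) = m.tri[3 * t + c] + 1; // 1-based
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}
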