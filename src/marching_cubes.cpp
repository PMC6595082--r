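#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Face-consistent marching cubes for (binary) 3-D scalar fields.
//
// Rather than a 256-entry triangle lookup table, each cell's surface patch is
// assembled from directed marching-squares segments traced on its six faces.
// On ambiguous faces (foreground corners on one diagonal) the
// foreground-connected resolution is applied; because both cells sharing a
// face see the same four values, the same segments are generated on either
// side, so the mesh is watertight and consistently oriented by construction.
// Surface vertices lie on grid edges at the iso crossing (edge midpoints for
// binary data at iso 0.5); non-triangular patch loops are fanned from their
// centroid, which handles the saddle ("tunnel") configurations exactly once.
//
// Orientation convention: segments are directed so that, viewed from outside
// the cell with the face normal towards the viewer, foreground lies to the
// right; the resulting triangle normals point from foreground to background
// and the total signed volume of the closed mesh is positive.

namespace {

// corner c = dx + 2*dy + 4*dz
const int CX[8] = {0,1,0,1,0,1,0,1};
const int CY[8] = {0,0,1,1,0,0,1,1};
const int CZ[8] = {0,0,0,0,1,1,1,1};

// six faces, corners cyclic counter-clockwise viewed from outside the cell
const int FACES[6][4] = {
  {0,4,6,2},  // x = 0
  {1,3,7,5},  // x = 1
  {0,1,5,4},  // y = 0
  {2,6,7,3},  // y = 1
  {0,2,3,1},  // z = 0
  {4,5,7,6}   // z = 1
};

struct MeshAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<int64_t,int> edge_vertex;
};

} // namespace

// [[Rcpp::export(name = ".mc_extract")]]
List mc_extract(NumericVector vol, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx < 2 || ny < 2 || nz < 2)
    stop("grid must have at least 2 voxels per axis");
  const double *v = REAL(vol);
  MeshAccum M;
  M.edge_vertex.reserve(1024);

  auto lin = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  // vertex on the grid edge between global corners a and b (differ on 1 axis)
  auto edge_vertex = [&](int ia,int ja,int ka,int ib,int jb,int kb) -> int {
    int axis, il = ia, jl = ja, kl = ka;
    if (ia != ib)      { axis = 0; il = std::min(ia, ib); }
    else if (ja != jb) { axis = 1; jl = std::min(ja, jb); }
    else               { axis = 2; kl = std::min(ka, kb); }
    int64_t key = 3 * lin(il, jl, kl) + axis;
    auto it = M.edge_vertex.find(key);
    if (it != M.edge_vertex.end()) return it->second;
    double vlo = v[lin(il, jl, kl)];
    int iu = il + (axis == 0), ju = jl + (axis == 1), ku = kl + (axis == 2);
    double vhi = v[lin(iu, ju, ku)];
    double t = (iso - vlo) / (vhi - vlo);
    double px = il, py = jl, pz = kl;
    if (axis == 0) px += t; else if (axis == 1) py += t; else pz += t;
    int idx = (int)M.vx.size();
    M.vx.push_back(px); M.vy.push_back(py); M.vz.push_back(pz);
    M.edge_vertex.emplace(key, idx);
    return idx;
  };

  std::vector<std::pair<int,int> > segs;   // per-cell directed segments
  segs.reserve(24);

  for (int k = 0; k < nz - 1; ++k)
  for (int j = 0; j < ny - 1; ++j)
  for (int i = 0; i < nx - 1; ++i) {
    bool fg[8]; int nfg = 0;
    for (int c = 0; c < 8; ++c) {
      fg[c] = v[lin(i + CX[c], j + CY[c], k + CZ[c])] > iso;
      nfg += fg[c];
    }
    if (nfg == 0 || nfg == 8) continue;
    segs.clear();

    for (int f = 0; f < 6; ++f) {
      const int *fc = FACES[f];
      bool b[4]; int m = 0;
      for (int q = 0; q < 4; ++q) {
        b[q] = fg[fc[q]];
        if (b[q]) m |= (1 << q);
      }
      if (m == 0 || m == 15) continue;

      // cut point on face edge (q, q+1 mod 4), as mesh vertex index
      auto cut = [&](int q) -> int {
        int ca = fc[q & 3], cb = fc[(q + 1) & 3];
        return edge_vertex(i + CX[ca], j + CY[ca], k + CZ[ca],
                           i + CX[cb], j + CY[cb], k + CZ[cb]);
      };

      if (m == 5 || m == 10) {
        // ambiguous face: foreground diagonal kept connected; one segment
        // clipping each background corner jbg, directed so fg stays right
        int bg0 = (m == 5) ? 1 : 0;
        for (int jbg = bg0; jbg < 4; jbg += 2)
          segs.push_back(std::make_pair(cut(jbg), cut((jbg + 3) & 3)));
      } else {
        // exactly one cyclic run of foreground corners from a to bEnd
        int a = -1;
        for (int q = 0; q < 4; ++q)
          if (b[q] && !b[(q + 3) & 3]) { a = q; break; }
        int bEnd = a;
        while (b[(bEnd + 1) & 3]) bEnd = (bEnd + 1) & 3;
        segs.push_back(std::make_pair(cut((a + 3) & 3), cut(bEnd)));
      }
    }

    // chain directed segments into closed loops
    int ns = (int)segs.size();
    std::vector<char> used(ns, 0);
    for (int s0 = 0; s0 < ns; ++s0) {
      if (used[s0]) continue;
      std::vector<int> loop;
      int cur = s0;
      while (!used[cur]) {
        used[cur] = 1;
        loop.push_back(segs[cur].first);
        int tail = segs[cur].second;
        int nxt = -1;
        for (int s = 0; s < ns; ++s)
          if (!used[s] && segs[s].first == tail) { nxt = s; break; }
        if (nxt < 0) {
          if (tail != segs[s0].first)
            stop("internal error: open surface loop in cell");
          break;
        }
        cur = nxt;
      }
      int L = (int)loop.size();
      if (L < 3) stop("internal error: degenerate surface loop");
      if (L == 3) {
        M.f0.push_back(loop[0]); M.f1.push_back(loop[1]); M.f2.push_back(loop[2]);
      } else {
        double cx = 0, cy = 0, cz = 0;
        for (int q = 0; q < L; ++q) {
          cx += M.vx[loop[q]]; cy += M.vy[loop[q]]; cz += M.vz[loop[q]];
        }
        int cidx = (int)M.vx.size();
        M.vx.push_back(cx / L); M.vy.push_back(cy / L); M.vz.push_back(cz / L);
        for (int q = 0; q < L; ++q) {
          M.f0.push_back(cidx);
          M.f1.push_back(loop[q]);
          M.f2.push_back(loop[(q + 1) % L]);
        }
      }
    }
  }

  int nv = (int)M.vx.size(), nf = (int)M.f0.size();
  NumericMatrix verts(nv, 3);
  for (int q = 0; q < nv; ++q) {
    verts(q, 0) = M.vx[q]; verts(q, 1) = M.vy[q]; verts(q, 2) = M.vz[q];
  }
  IntegerMatrix faces(nf, 3);
  for (int q = 0; q < nf; ++q) {
    faces(q, 0) = M.f0[q] + 1; faces(q, 1) = M.f1[q] + 1; faces(q, 2) = M.f2[q] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// [[Rcpp::export(name = ".mesh_signed_volume")]]
double mesh_signed_volume(NumericMatrix verts, IntegerMatrix faces) {
  double vol = 0.0;
  int nf = faces.nrow();
  for (int q = 0; q < nf; ++q) {
    int a = faces(q,0) - 1, b = faces(q,1) - 1, c = faces(q,2) - 1;
    double ax = verts(a,0), ay = verts(a,1), az = verts(a,2);
    double bx = verts(b,0), by = verts(b,1), bz = verts(b,2);
    double cx = verts(c,0), cy = verts(c,1), cz = verts(c,2);
    vol += ax * (by * cz - bz * cy)
         - ay * (bx * cz - bz * cx)
         + az * (bx * cy - by * cx);
  }
  return vol / 6.0;
}
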