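#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface extraction.
//
// Each grid cube is split into 6 tetrahedra sharing the main diagonal
// c0-c6; the split is translation-invariant so faces shared by adjacent
// cubes are triangulated identically and the output surface is conforming
// (watertight when the >= iso region does not touch the grid boundary).
// Vertices are linearly interpolated on tetrahedron edges; every such edge
// connects two grid points, so vertices are deduplicated by the (sorted)
// grid-point id pair. The tetrahedral decomposition avoids the face
// ambiguities of cube case tables.
// ---------------------------------------------------------------------------

static const int CUBE_OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// 6 tetrahedra around the 0-6 diagonal
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

// [[Rcpp::export]]
List mt_isosurface(NumericVector vol, IntegerVector dims, double iso,
                   NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = vol.begin();
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto world = [&](double i, double j, double k, double *out) {
    out[0] = origin[0] + i * spacing[0];
    out[1] = origin[1] + j * spacing[1];
    out[2] = origin[2] + k * spacing[2];
  };

  // get-or-create interpolated vertex on grid edge (a,b)
  auto edge_vert = [&](int64_t ga, int64_t gb, const double *pa, const double *pb,
                       double fa, double fb) -> int {
    uint64_t key;
    if (ga < gb) key = ((uint64_t)ga << 32) | (uint64_t)gb;
    else         key = ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  };

  double cf[8], cp[8][3];
  int64_t cg[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE_OFF[c][0], jj = j + CUBE_OFF[c][1], kk = k + CUBE_OFF[c][2];
          cg[c] = gid(ii, jj, kk);
          double val = f[cg[c]];
          if (val == iso) val = iso + 1e-9 * (std::abs(iso) + 1.0); // avoid grid-point hits
          cf[c] = val;
          world(ii, jj, kk, cp[c]);
          if (val >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int tt = 0; tt < 6; ++tt) {
          const int *T = TETS[tt];
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (cf[T[v]] >= iso) in_idx[nin++] = T[v];
            else out_idx[nout++] = T[v];
          }
          if (nin == 0 || nin == 4) continue;

          auto emit = [&](int a, int b, int c) {
            // orient so the normal points away from the inside region:
            // reference = vector from triangle centroid to an inside vertex
            double cx = (vx[a] + vx[b] + vx[c]) / 3.0;
            double cy = (vy[a] + vy[b] + vy[c]) / 3.0;
            double cz = (vz[a] + vz[b] + vz[c]) / 3.0;
            const double *pin = cp[in_idx[0]];
            double rx = pin[0] - cx, ry = pin[1] - cy, rz = pin[2] - cz;
            double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
            double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
            double nxv = uy * wz - uz * wy;
            double nyv = uz * wx - ux * wz;
            double nzv = ux * wy - uy * wx;
            if (nxv * rx + nyv * ry + nzv * rz > 0) { int s = b; b = c; c = s; }
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          };

          if (nin == 1) {
            int a = in_idx[0];
            int e0 = edge_vert(cg[a], cg[out_idx[0]], cp[a], cp[out_idx[0]], cf[a], cf[out_idx[0]]);
            int e1 = edge_vert(cg[a], cg[out_idx[1]], cp[a], cp[out_idx[1]], cf[a], cf[out_idx[1]]);
            int e2 = edge_vert(cg[a], cg[out_idx[2]], cp[a], cp[out_idx[2]], cf[a], cf[out_idx[2]]);
            emit(e0, e1, e2);
          } else if (nin == 3) {
            int a = out_idx[0];
            int e0 = edge_vert(cg[a], cg[in_idx[0]], cp[a], cp[in_idx[0]], cf[a], cf[in_idx[0]]);
            int e1 = edge_vert(cg[a], cg[in_idx[1]], cp[a], cp[in_idx[1]], cf[a], cf[in_idx[1]]);
            int e2 = edge_vert(cg[a], cg[in_idx[2]], cp[a], cp[in_idx[2]], cf[a], cf[in_idx[2]]);
            emit(e0, e1, e2);
          } else { // nin == 2: quad split into two triangles
            int a0 = in_idx[0], a1 = in_idx[1], b0 = out_idx[0], b1 = out_idx[1];
            int e00 = edge_vert(cg[a0], cg[b0], cp[a0], cp[b0], cf[a0], cf[b0]);
            int e01 = edge_vert(cg[a0], cg[b1], cp[a0], cp[b1], cf[a0], cf[b1]);
            int e10 = edge_vert(cg[a1], cg[b0], cp[a1], cp[b0], cf[a1], cf[b0]);
            int e11 = edge_vert(cg[a1], cg[b1], cp[a1], cp[b1], cf[a1], cf[b1]);
            emit(e00, e01, e11);
            emit(e00, e11, e10);
          }
        }
      }
    }
  }

  int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i,0) = tri[3*i] + 1; F(i,1) = tri[3*i+1] + 1; F(i,2) = tri[3*i+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// 26-connected component containing a seed voxel (BFS flood fill).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector flood_fill_26(LogicalVector mask, IntegerVector dims,
                            IntegerVector seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  LogicalVector out(mask.size(), false);
  int si = seed[0], sj = seed[1], sk = seed[2]; // 0-based
  if (si < 0 || sj < 0 || sk < 0 || si >= nx || sj >= ny || sk >= nz)
    stop("seed outside grid");
  if (!mask[idx(si, sj, sk)]) return out; // caller handles seed-not-in-mask
  std::queue<int> q;
  out[idx(si, sj, sk)] = true;
  q.push(idx(si, sj, sk));
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int k = cur / (nx * ny), rem = cur % (nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int id = idx(ii, jj, kk);
          if (mask[id] && !out[id]) { out[id] = true; q.push(id); }
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest neighbours via a uniform spatial grid (ties broken by lowest
// reference index, matching a first-strict-minimum brute-force scan).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector nn_index(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  if (nr == 0) stop("empty reference point set");

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int r = 0; r < nr; ++r)
    for (int d = 0; d < 3; ++d) {
      double v = ref(r,d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double span = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-9});
  double h = std::cbrt(std::max(1e-12,
      (hi[0]-lo[0]+1e-9) * (hi[1]-lo[1]+1e-9) * (hi[2]-lo[2]+1e-9) / nr));
  h = std::max(h, span / 128.0);
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, (int)std::floor((hi[d]-lo[d]) / h) + 1);

  auto cell_of = [&](double x, double y, double z, int *c) {
    c[0] = std::min(ng[0]-1, std::max(0, (int)std::floor((x-lo[0]) / h)));
    c[1] = std::min(ng[1]-1, std::max(0, (int)std::floor((y-lo[1]) / h)));
    c[2] = std::min(ng[2]-1, std::max(0, (int)std::floor((z-lo[2]) / h)));
  };
  int ncell = ng[0]*ng[1]*ng[2];
  std::vector<int> counts(ncell + 1, 0), start(ncell + 1, 0);
  std::vector<int> cellidx(nr);
  for (int r = 0; r < nr; ++r) {
    int c[3]; cell_of(ref(r,0), ref(r,1), ref(r,2), c);
    cellidx[r] = c[0] + ng[0]*(c[1] + ng[1]*c[2]);
    counts[cellidx[r]]++;
  }
  for (int i = 0; i < ncell; ++i) start[i+1] = start[i] + counts[i];
  std::vector<int> bucket(nr), fill(start.begin(), start.end());
  for (int r = 0; r < nr; ++r) bucket[fill[cellidx[r]]++] = r;  // ascending idx

  for (int q = 0; q < nq; ++q) {
    double qx = query(q,0), qy = query(q,1), qz = query(q,2);
    int qc[3]; cell_of(qx, qy, qz, qc);
    double best = R_PosInf; int bi = -1;
    int maxring = std::max({ng[0], ng[1], ng[2]});
    for (int ring = 0; ring <= maxring; ++ring) {
      // once a neighbour is known, stop when the nearest possible point in
      // this ring is farther than it
      if (bi >= 0) {
        double dmin = (ring - 1) * h;  // conservative lower bound
        if (dmin > 0 && dmin * dmin > best) break;
      }
      for (int dk = -ring; dk <= ring; ++dk) {
        int k = qc[2] + dk; if (k < 0 || k >= ng[2]) continue;
        for (int dj = -ring; dj <= ring; ++dj) {
          int j = qc[1] + dj; if (j < 0 || j >= ng[1]) continue;
          for (int di = -ring; di <= ring; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != ring)
              continue;  // shell only
            int i = qc[0] + di; if (i < 0 || i >= ng[0]) continue;
            int c = i + ng[0]*(j + ng[1]*k);
            for (int s = start[c]; s < start[c+1]; ++s) {
              int r = bucket[s];
              double dx = ref(r,0)-qx, dy = ref(r,1)-qy, dz = ref(r,2)-qz;
              double d = dx*dx + dy*dy + dz*dz;
              if (d < best || (d == best && r < bi)) { best = d; bi = r; }
            }
          }
        }
      }
    }
    out[q] = bi + 1;
  }
  return out;
}
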