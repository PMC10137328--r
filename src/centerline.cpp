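// Medial centerline extraction from a binary object mask, in the spirit of
// TEASAR (Sato et al. 2000): geodesic paths through the object whose edge
// costs are penalized away from the medial axis via the Euclidean distance
// transform. The object is assumed 26-connected. Returns one primary path
// between the two geodesically most distant voxels, plus branch paths added
// until every object voxel lies within its local radius of the skeleton.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

struct QE {
  double d;
  int v;
};
struct QCmp {
  bool operator()(const QE& a, const QE& b) const { return a.d > b.d; }
};

// [[Rcpp::export]]
List cpp_centerline(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                    NumericVector edt, double gamma, int max_branches,
                    double cover_slack) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny, ntot = (R_xlen_t)nz * ny * nx;

  // node table
  std::vector<R_xlen_t> vox;   // node -> linear index
  std::vector<int> node(ntot, -1);
  for (R_xlen_t i = 0; i < ntot; ++i)
    if (mask[i]) {
      node[i] = (int)vox.size();
      vox.push_back(i);
    }
  int n = (int)vox.size();
  if (n == 0) return List::create(_["paths"] = List());

  std::vector<double> redt(n);
  double maxedt = 0.0;
  for (int i = 0; i < n; ++i) {
    redt[i] = edt[vox[i]];
    if (redt[i] > maxedt) maxedt = redt[i];
  }
  if (maxedt <= 0) maxedt = 1.0;

  // 26-neighborhood with physical step lengths
  int offs[26];
  int dzs[26], dys[26], dxs[26];
  double len[26];
  int nn = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        dzs[nn] = dz; dys[nn] = dy; dxs[nn] = dx;
        offs[nn] = dz + dy * (int)sy + dx * (int)sx;
        double lz = dz * spacing[0], ly = dy * spacing[1], lx = dx * spacing[2];
        len[nn] = std::sqrt(lz * lz + ly * ly + lx * lx);
        ++nn;
      }

  const double INF = 1e300;
  std::vector<double> dist(n);
  std::vector<int> pred(n);
  std::vector<double> rootr(n); // EDT radius of the source each voxel drains to

  // Dijkstra from a set of sources. penal: multiply edge length by a factor
  // that grows away from the medial axis. stopmask: terminate when a flagged
  // node is settled (returns it); -1 if none/absent. src_offset shifts each
  // source's starting distance (negative offsets implement "radius ball"
  // coverage: the settled value is min over sources of geodesic + offset).
  auto dijkstra = [&](const std::vector<int>& sources, bool penal,
                      const std::vector<char>* stopmask,
                      double src_radius_scale) -> int {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(pred.begin(), pred.end(), -1);
    std::fill(rootr.begin(), rootr.end(), 0.0);
    std::priority_queue<QE, std::vector<QE>, QCmp> pq;
    for (int s : sources) {
      dist[s] = -src_radius_scale * redt[s];
      rootr[s] = redt[s];
      pq.push({dist[s], s});
    }
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      int u = top.v;
      if (top.d > dist[u]) continue;
      if (stopmask && (*stopmask)[u]) return u;
      R_xlen_t lu = vox[u];
      int z = (int)(lu % nz), y = (int)((lu / nz) % ny), x = (int)(lu / sx);
      for (int k = 0; k < 26; ++k) {
        int z2 = z + dzs[k], y2 = y + dys[k], x2 = x + dxs[k];
        if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= nz || y2 >= ny || x2 >= nx)
          continue;
        int v = node[lu + offs[k]];
        if (v < 0) continue;
        double w = len[k];
        if (penal) {
          double rel = 1.0 - redt[v] / maxedt;
          w *= 1.0 + gamma * rel * rel;
        }
        double nd = dist[u] + w;
        if (nd < dist[v]) {
          dist[v] = nd;
          pred[v] = u;
          rootr[v] = rootr[u];
          pq.push({nd, v});
        }
      }
    }
    return -1;
  };

  auto argmax_finite = [&]() {
    int best = -1;
    double bv = -1.0;
    for (int i = 0; i < n; ++i)
      if (dist[i] < INF && dist[i] > bv) {
        bv = dist[i];
        best = i;
      }
    return best;
  };

  // 1) plain geodesic sweep from the most interior voxel -> endpoint A
  int seed = 0;
  for (int i = 1; i < n; ++i)
    if (redt[i] > redt[seed]) seed = i;
  dijkstra({seed}, false, nullptr, 0.0);
  int A = argmax_finite();
  // 2) penalized sweep from A -> endpoint B, primary path by predecessors
  dijkstra({A}, true, nullptr, 0.0);
  int B = argmax_finite();

  std::vector<char> onskel(n, 0);
  List paths;
  std::vector<int> skel_nodes;
  {
    std::vector<int> path;
    for (int v = B; v != -1; v = pred[v]) path.push_back(v);
    IntegerVector pv(path.size());
    for (size_t i = 0; i < path.size(); ++i) {
      pv[i] = (int)(vox[path[i]] + 1);   // 1-based linear index for R
      onskel[path[i]] = 1;
      skel_nodes.push_back(path[i]);
    }
    paths.push_back(pv);
  }

  // 3) branches until covered: voxel v is covered when its plain geodesic
  // distance to the skeleton is within cover_slack times the local radius of
  // the skeleton node it drains to (TEASAR's "radius ball" coverage).
  double tol = std::sqrt(spacing[0] * spacing[0] + spacing[1] * spacing[1] +
                         spacing[2] * spacing[2]);
  for (int b = 0; b < max_branches; ++b) {
    dijkstra(skel_nodes, false, nullptr, cover_slack);
    int worst = -1;
    double wv = tol;
    for (int i = 0; i < n; ++i) {
      if (onskel[i] || dist[i] >= INF) continue;
      if (dist[i] > wv) {
        wv = dist[i];
        worst = i;
      }
    }
    if (worst < 0) break;
    int hit = dijkstra({worst}, true, &onskel, 0.0);
    if (hit < 0) break;
    std::vector<int> path;
    for (int v = hit; v != -1; v = pred[v]) path.push_back(v);
    // path runs junction -> tip; reverse so it reads tip -> junction
    IntegerVector pv(path.size());
    for (size_t i = 0; i < path.size(); ++i) {
      pv[i] = (int)(vox[path[i]] + 1);
      if (!onskel[path[i]]) {
        onskel[path[i]] = 1;
        skel_nodes.push_back(path[i]);
      }
    }
    paths.push_back(pv);
  }

  return List::create(_["paths"] = paths);
}
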