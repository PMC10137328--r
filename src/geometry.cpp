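// Voxel-set and point-set geometry helpers: boundary voxels, 26-connected
// component labeling, farthest point pairs, and edge-connected triangle
// patches (union-find).
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <functional>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// TRUE where a mask voxel has a 6-neighbor outside the mask (grid border
// counts as outside).
// [[Rcpp::export]]
LogicalVector cpp_boundary(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  LogicalVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + y * sy + (R_xlen_t)x * sx;
        if (!mask[i]) continue;
        bool b = (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 ||
                  x == nx - 1);
        if (!b)
          b = !mask[i - 1] || !mask[i + 1] || !mask[i - sy] || !mask[i + sy] ||
              !mask[i - sx] || !mask[i + sx];
        out[i] = b;
      }
  return out;
}

// Split nonzero labels into 26-connected components (a component never spans
// two different input labels). Returns per-voxel component id (1..n, 0 for
// background) plus the original label of each component.
// [[Rcpp::export]]
List cpp_label_components(IntegerVector lab, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny, n = (R_xlen_t)nz * ny * nx;
  IntegerVector comp(n, 0);
  std::vector<int> orig;
  std::vector<R_xlen_t> stack;
  int ncomp = 0;

  int dzs[26], dys[26], dxs[26], nn = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        dzs[nn] = dz; dys[nn] = dy; dxs[nn] = dx; ++nn;
      }

  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        R_xlen_t i0 = z0 + y0 * sy + (R_xlen_t)x0 * sx;
        if (lab[i0] == 0 || comp[i0] != 0) continue;
        ++ncomp;
        int l = lab[i0];
        orig.push_back(l);
        comp[i0] = ncomp;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back();
          stack.pop_back();
          int z = (int)(i % nz);
          int y = (int)((i / nz) % ny);
          int x = (int)(i / sx);
          for (int k = 0; k < 26; ++k) {
            int z2 = z + dzs[k], y2 = y + dys[k], x2 = x + dxs[k];
            if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= nz || y2 >= ny || x2 >= nx)
              continue;
            R_xlen_t j = z2 + y2 * sy + (R_xlen_t)x2 * sx;
            if (lab[j] == l && comp[j] == 0) {
              comp[j] = ncomp;
              stack.push_back(j);
            }
          }
        }
      }
  comp.attr("dim") = dim;
  return List::create(_["comp"] = comp, _["n"] = ncomp,
                      _["orig"] = IntegerVector(orig.begin(), orig.end()));
}

// Farthest pair of points. Exact O(n^2) up to exact_limit points; beyond
// that, candidate endpoints are the extreme points along ndirs
// quasi-uniform (Fibonacci sphere) directions, then exact search among
// candidates. Returns c(distance, i, j) with 1-based indices.
// [[Rcpp::export]]
NumericVector cpp_max_pair(NumericMatrix P, int exact_limit, int ndirs) {
  int n = P.nrow();
  if (n == 0) return NumericVector::create(0.0, NA_REAL, NA_REAL);
  if (n == 1) return NumericVector::create(0.0, 1, 1);

  std::vector<int> cand;
  if (n <= exact_limit) {
    cand.resize(n);
    for (int i = 0; i < n; ++i) cand[i] = i;
  } else {
    std::vector<char> used(n, 0);
    double ga = M_PI * (3.0 - std::sqrt(5.0));
    for (int d = 0; d < ndirs; ++d) {
      double zc = 1.0 - 2.0 * (d + 0.5) / ndirs;
      double r = std::sqrt(std::max(0.0, 1.0 - zc * zc));
      double th = ga * d;
      double dir[3] = {zc, r * std::cos(th), r * std::sin(th)};
      double bmax = -DBL_MAX, bmin = DBL_MAX;
      int imax = 0, imin = 0;
      for (int i = 0; i < n; ++i) {
        double s = dir[0] * P(i, 0) + dir[1] * P(i, 1) + dir[2] * P(i, 2);
        if (s > bmax) { bmax = s; imax = i; }
        if (s < bmin) { bmin = s; imin = i; }
      }
      if (!used[imax]) { used[imax] = 1; cand.push_back(imax); }
      if (!used[imin]) { used[imin] = 1; cand.push_back(imin); }
    }
  }

  double best = -1.0;
  int bi = 0, bj = 0;
  int m = (int)cand.size();
  for (int a = 0; a < m; ++a) {
    int i = cand[a];
    for (int b = a + 1; b < m; ++b) {
      int j = cand[b];
      double dz = P(i, 0) - P(j, 0), dy = P(i, 1) - P(j, 1),
             dx = P(i, 2) - P(j, 2);
      double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 > best) { best = d2; bi = i; bj = j; }
    }
  }
  return NumericVector::create(std::sqrt(best), bi + 1, bj + 1);
}

// Connected components of selected triangles under shared-edge adjacency,
// restricted to triangles with the same group id (used to split contact
// patches by ER object). Returns per-face patch id (0 = not selected).
// [[Rcpp::export]]
IntegerVector cpp_edge_components(IntegerMatrix F, IntegerVector fgroup,
                                  LogicalVector sel) {
  int nf = F.nrow();
  std::vector<int> parent(nf);
  for (int i = 0; i < nf; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  };

  std::unordered_map<long long, int> edge_last; // edge key -> last face seen
  for (int f = 0; f < nf; ++f) {
    if (!sel[f]) continue;
    for (int s = 0; s < 3; ++s) {
      long long v1 = F(f, s), v2 = F(f, (s + 1) % 3);
      if (v1 > v2) std::swap(v1, v2);
      long long key = (v1 << 32) | v2;
      auto it = edge_last.find(key);
      if (it == edge_last.end()) {
        edge_last[key] = f;
      } else {
        int g = it->second;
        if (fgroup[g] == fgroup[f]) unite(g, f);
        it->second = f;
      }
    }
  }
  IntegerVector out(nf, 0);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int f = 0; f < nf; ++f) {
    if (!sel[f]) continue;
    int r = find(f);
    auto it = remap.find(r);
    int id;
    if (it == remap.end()) {
      id = ++next;
      remap[r] = id;
    } else {
      id = it->second;
    }
    out[f] = id;
  }
  return out;
}
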