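// Capped nearest-distance queries from points to a triangle mesh, using a
// uniform spatial hash with expanding-shell search. Distances beyond the cap
// are reported as Inf (sufficient for contact-site detection, where only
// gaps up to a few multiples of the 25 nm criterion matter).
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Squared distance from point p to triangle (a,b,c); Ericson, Real-Time
// Collision Detection, ch. 5.1.5.
static double pt_tri_d2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) {
      bp[i] = p[i] - b[i];
      cp[i] = p[i] - c[i];
    }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      } else if (d6 >= 0.0 && d5 <= d6) {
        q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double w = d2 / (d2 - d6);
          for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double v = vb * denom, w = vc * denom;
            for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
List cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                         double cap) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np, R_PosInf);
  IntegerVector tri(np, NA_INTEGER);
  if (nf == 0 || np == 0) return List::create(_["dist"] = dist, _["tri"] = tri);

  double mn[3] = {DBL_MAX, DBL_MAX, DBL_MAX};
  double mx[3] = {-DBL_MAX, -DBL_MAX, -DBL_MAX};
  for (int i = 0; i < V.nrow(); ++i)
    for (int c = 0; c < 3; ++c) {
      if (V(i, c) < mn[c]) mn[c] = V(i, c);
      if (V(i, c) > mx[c]) mx[c] = V(i, c);
    }

  // adaptive cell: a few typical triangle extents, but not so small that the
  // shell search explodes for large caps
  double tri_ext = 0.0;
  int nsamp = std::min(nf, 256);
  for (int s = 0; s < nsamp; ++s) {
    int f = (int)((long long)s * nf / nsamp);
    double lo[3] = {DBL_MAX, DBL_MAX, DBL_MAX};
    double hi[3] = {-DBL_MAX, -DBL_MAX, -DBL_MAX};
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int c = 0; c < 3; ++c) {
        double vv = V(vi, c);
        if (vv < lo[c]) lo[c] = vv;
        if (vv > hi[c]) hi[c] = vv;
      }
    }
    tri_ext += std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  }
  tri_ext /= nsamp;
  double cell = std::max(3.0 * tri_ext, cap / 8.0);
  if (cell <= 0) cell = cap > 0 ? cap : 1.0;
  int smax = (int)std::ceil(cap / cell) + 1;

  long long nc[3];
  for (int c = 0; c < 3; ++c)
    nc[c] = (long long)std::floor((mx[c] - mn[c]) / cell) + 1;
  size_t nbins = (size_t)nc[0] * nc[1] * nc[2];
  auto keyof = [&](long long cz, long long cy, long long cx) {
    return (size_t)((cz * nc[1] + cy) * nc[2] + cx);
  };
  // CSR layout: two passes (count, fill) into a dense bin grid
  std::vector<int> bin_start(nbins + 1, 0);
  std::vector<long long> fc0(3 * nf), fc1(3 * nf);
  for (int f = 0; f < nf; ++f) {
    double lo[3] = {DBL_MAX, DBL_MAX, DBL_MAX};
    double hi[3] = {-DBL_MAX, -DBL_MAX, -DBL_MAX};
    for (int s = 0; s < 3; ++s) {
      int vi = F(f, s) - 1;
      for (int c = 0; c < 3; ++c) {
        double vv = V(vi, c);
        if (vv < lo[c]) lo[c] = vv;
        if (vv > hi[c]) hi[c] = vv;
      }
    }
    for (int c = 0; c < 3; ++c) {
      fc0[3 * f + c] = (long long)std::floor((lo[c] - mn[c]) / cell);
      fc1[3 * f + c] = (long long)std::floor((hi[c] - mn[c]) / cell);
    }
    for (long long cz = fc0[3 * f]; cz <= fc1[3 * f]; ++cz)
      for (long long cy = fc0[3 * f + 1]; cy <= fc1[3 * f + 1]; ++cy)
        for (long long cx = fc0[3 * f + 2]; cx <= fc1[3 * f + 2]; ++cx)
          ++bin_start[keyof(cz, cy, cx) + 1];
  }
  for (size_t bform = 1; bform <= nbins; ++bform)
    bin_start[bform] += bin_start[bform - 1];
  std::vector<int> bin_tris(bin_start[nbins]);
  std::vector<int> cursor(bin_start.begin(), bin_start.end() - 1);
  for (int f = 0; f < nf; ++f) {
    for (long long cz = fc0[3 * f]; cz <= fc1[3 * f]; ++cz)
      for (long long cy = fc0[3 * f + 1]; cy <= fc1[3 * f + 1]; ++cy)
        for (long long cx = fc0[3 * f + 2]; cx <= fc1[3 * f + 2]; ++cx)
          bin_tris[cursor[keyof(cz, cy, cx)]++] = f;
  }

  double cap2 = cap * cap;
  double a[3], b[3], c3[3], p[3];
  for (int i = 0; i < np; ++i) {
    for (int c = 0; c < 3; ++c) p[c] = P(i, c);
    // bbox quick reject
    bool out = false;
    for (int c = 0; c < 3; ++c)
      if (p[c] < mn[c] - cap || p[c] > mx[c] + cap) { out = true; break; }
    if (out) continue;

    long long pc[3];
    for (int c = 0; c < 3; ++c)
      pc[c] = (long long)std::floor((p[c] - mn[c]) / cell);

    double best = cap2;
    int besttri = NA_INTEGER;
    auto scan_cell = [&](long long cz, long long cy, long long cx) {
      if (cz < 0 || cy < 0 || cx < 0 || cz >= nc[0] || cy >= nc[1] ||
          cx >= nc[2])
        return;
      size_t bi = keyof(cz, cy, cx);
      for (int t2 = bin_start[bi]; t2 < bin_start[bi + 1]; ++t2) {
        int f = bin_tris[t2];
        for (int k = 0; k < 3; ++k) {
          int vi = F(f, k) - 1;
          double* dst = (k == 0) ? a : (k == 1) ? b : c3;
          dst[0] = V(vi, 0); dst[1] = V(vi, 1); dst[2] = V(vi, 2);
        }
        double d2 = pt_tri_d2(p, a, b, c3);
        if (d2 <= best) {
          best = d2;
          besttri = f + 1;
        }
      }
    };
    scan_cell(pc[0], pc[1], pc[2]);
    for (int s = 1; s <= smax; ++s) {
      // a triangle in a farther shell is at least (s-1)*cell away
      if (besttri != NA_INTEGER &&
          best <= (double)(s - 1) * cell * (double)(s - 1) * cell)
        break;
      // enumerate the surface of the Chebyshev shell of radius s
      for (long long dy = -s; dy <= s; ++dy)
        for (long long dx = -s; dx <= s; ++dx) {
          scan_cell(pc[0] - s, pc[1] + dy, pc[2] + dx);
          scan_cell(pc[0] + s, pc[1] + dy, pc[2] + dx);
        }
      for (long long dz = -s + 1; dz <= s - 1; ++dz)
        for (long long dx = -s; dx <= s; ++dx) {
          scan_cell(pc[0] + dz, pc[1] - s, pc[2] + dx);
          scan_cell(pc[0] + dz, pc[1] + s, pc[2] + dx);
        }
      for (long long dz = -s + 1; dz <= s - 1; ++dz)
        for (long long dy = -s + 1; dy <= s - 1; ++dy) {
          scan_cell(pc[0] + dz, pc[1] + dy, pc[2] - s);
          scan_cell(pc[0] + dz, pc[1] + dy, pc[2] + s);
        }
    }
    if (besttri != NA_INTEGER) {
      dist[i] = std::sqrt(best);
      tri[i] = besttri;
    }
  }
  return List::create(_["dist"] = dist, _["tri"] = tri);
}
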