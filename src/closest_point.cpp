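#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Closest point on a triangle (a, b, c) to point p.
// Ericson, "Real-Time Collision Detection", section 5.1.5.
static inline void closestPointTriangle(const double* p,
                                        const double* a, const double* b,
                                        const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid {
  double lo[3];
  double cell;
  int n[3];
  std::vector<std::vector<int> > bins; // triangle ids per cell

  int idx(int ix, int iy, int iz) const {
    return (iz * n[1] + iy) * n[0] + ix;
  }
  int clampc(double x, int axis) const {
    int i = (int)std::floor((x - lo[axis]) / cell);
    if (i < 0) i = 0;
    if (i >= n[axis]) i = n[axis] - 1;
    return i;
  }
};

static void buildGrid(const NumericMatrix& V, const IntegerMatrix& F, TriGrid& g) {
  int nv = V.nrow(), nf = F.nrow();
  double hi[3];
  for (int a = 0; a < 3; ++a) { g.lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < nv; ++i)
    for (int a = 0; a < 3; ++a) {
      double x = V(i, a);
      if (x < g.lo[a]) g.lo[a] = x;
      if (x > hi[a]) hi[a] = x;
    }
  double ext[3], diag = 0.0;
  for (int a = 0; a < 3; ++a) { ext[a] = hi[a] - g.lo[a]; diag += ext[a]*ext[a]; }
  diag = std::sqrt(diag);
  if (diag <= 0.0) diag = 1.0;
  // aim for roughly one triangle-AABB insertion per cell
  double target = std::cbrt((double)std::max(nf, 1));
  g.cell = std::max(diag / (4.0 * target), diag * 1e-6);
  for (int a = 0; a < 3; ++a) {
    g.n[a] = std::max(1, (int)std::ceil(ext[a] / g.cell) );
    g.n[a] = std::min(g.n[a], 256);
  }
  // recompute cell so the grid covers the bbox with the clamped resolution
  double need = 0.0;
  for (int a = 0; a < 3; ++a) need = std::max(need, ext[a] / g.n[a]);
  g.cell = std::max(g.cell, need + 1e-12);
  g.bins.assign((size_t)g.n[0] * g.n[1] * g.n[2], std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int a = 0; a < 3; ++a) {
        double x = V(vi, a);
        if (x < tlo[a]) tlo[a] = x;
        if (x > thi[a]) thi[a] = x;
      }
    }
    int i0 = g.clampc(tlo[0], 0), i1 = g.clampc(thi[0], 0);
    int j0 = g.clampc(tlo[1], 1), j1 = g.clampc(thi[1], 1);
    int k0 = g.clampc(tlo[2], 2), k1 = g.clampc(thi[2], 2);
    for (int iz = k0; iz <= k1; ++iz)
      for (int iy = j0; iy <= j1; ++iy)
        for (int ix = i0; ix <= i1; ++ix)
          g.bins[g.idx(ix, iy, iz)].push_back(f);
  }
}

// [[Rcpp::export(name = ".cpp_closest_point")]]
List cpp_closest_point(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nf = F.nrow(), nq = Q.nrow();
  TriGrid g;
  buildGrid(V, F, g);

  // flat per-triangle corner coordinates (avoids Rcpp indexing in the hot loop)
  std::vector<double> tv((size_t)nf * 9);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      tv[(size_t)f * 9 + k * 3 + 0] = V(vi, 0);
      tv[(size_t)f * 9 + k * 3 + 1] = V(vi, 1);
      tv[(size_t)f * 9 + k * 3 + 2] = V(vi, 2);
    }
  }

  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);
  std::vector<int> stamp(nf, -1);

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    int ci[3];
    for (int a = 0; a < 3; ++a) ci[a] = g.clampc(p[a], a);

    double best = std::numeric_limits<double>::infinity();
    double bestPt[3] = {0, 0, 0};
    int bestF = -1;
    int maxRing = std::max(std::max(g.n[0], g.n[1]), g.n[2]);

    for (int ring = 0; ring <= maxRing; ++ring) {
      // once a hit exists, stop when closer hits are geometrically impossible:
      // cells at Chebyshev distance `ring` are at least (ring-1)*cell away
      if (bestF >= 0 && (double)(ring - 1) * g.cell > best) break;
      bool any = false;
      int x0 = ci[0] - ring, x1 = ci[0] + ring;
      int y0 = ci[1] - ring, y1 = ci[1] + ring;
      int z0 = ci[2] - ring, z1 = ci[2] + ring;
      for (int iz = z0; iz <= z1; ++iz) {
        if (iz < 0 || iz >= g.n[2]) continue;
        for (int iy = y0; iy <= y1; ++iy) {
          if (iy < 0 || iy >= g.n[1]) continue;
          for (int ix = x0; ix <= x1; ++ix) {
            if (ix < 0 || ix >= g.n[0]) continue;
            // only the shell of the ring (interior already visited)
            if (ring > 0 &&
                std::abs(ix - ci[0]) != ring &&
                std::abs(iy - ci[1]) != ring &&
                std::abs(iz - ci[2]) != ring) continue;
            any = true;
            const std::vector<int>& bin = g.bins[g.idx(ix, iy, iz)];
            for (size_t t = 0; t < bin.size(); ++t) {
              int f = bin[t];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              const double* tc = &tv[(size_t)f * 9];
              double cp[3];
              closestPointTriangle(p, tc, tc + 3, tc + 6, cp);
              double dx = cp[0]-p[0], dy = cp[1]-p[1], dz = cp[2]-p[2];
              double d = std::sqrt(dx*dx + dy*dy + dz*dz);
              if (d < best) {
                best = d; bestF = f;
                bestPt[0] = cp[0]; bestPt[1] = cp[1]; bestPt[2] = cp[2];
              }
            }
          }
        }
      }
      if (!any && bestF >= 0) break;
    }

    P(q, 0) = bestPt[0]; P(q, 1) = bestPt[1]; P(q, 2) = bestPt[2];
    D[q] = best;
    FI[q] = bestF + 1;
  }

  return List::create(_["point"] = P, _["distance"] = D, _["face"] = FI);
}
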