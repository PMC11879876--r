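#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// minimum-image distance between points a and b in an orthorhombic box
inline double mi_dist(const double* a, const double* b, const double* L) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    d -= L[k] * std::round(d / L[k]);
    s += d * d;
  }
  return std::sqrt(s);
}

inline void mi_disp(const double* a, const double* b, const double* L, double* out) {
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    d -= L[k] * std::round(d / L[k]);
    out[k] = d;
  }
}

// clearance radius at c: distance to nearest bead surface, capped
double clearance(const double* c, const NumericMatrix& beads, const double* L,
                 double r_bead, double r_cap, int* nearest) {
  int m = beads.nrow();
  double best = R_PosInf;
  int bi = -1;
  for (int i = 0; i < m; ++i) {
    double b[3] = {beads(i, 0), beads(i, 1), beads(i, 2)};
    double d = mi_dist(c, b, L);
    if (d < best) { best = d; bi = i; }
  }
  if (nearest) *nearest = bi;
  if (bi < 0) return r_cap;
  return std::min(best - r_bead, r_cap);
}

} // namespace

// Largest sphere containing each probe point without overlapping any bead.
// Local constrained ascent: the sphere center climbs the clearance field
// (distance to nearest bead surface) while the probe is kept inside the
// sphere by pulling the center back toward the probe along the line to it.
// Multi-start: plain start at the probe plus one start nudged away from each
// of the three nearest beads reduces local-maximum misses.
// Returns diameter (capped at min box edge), final center, convergence flag.
// [[Rcpp::export(name = ".mesh_probe_cpp")]]
List mesh_probe_cpp(NumericMatrix beads, NumericVector box, NumericMatrix probes,
                    double r_bead, double tol, int max_iter) {
  double L[3] = {box[0], box[1], box[2]};
  double r_cap = std::min(std::min(L[0], L[1]), L[2]) / 2.0;
  int n = probes.nrow(), m = beads.nrow();
  NumericVector diam(n);
  NumericMatrix centers(n, 3);
  LogicalVector inside_bead(n), capped(n);

  for (int ip = 0; ip < n; ++ip) {
    double p[3] = {probes(ip, 0), probes(ip, 1), probes(ip, 2)};
    if (m == 0) {
      diam[ip] = 2.0 * r_cap;
      for (int k = 0; k < 3; ++k) centers(ip, k) = p[k];
      capped[ip] = true;
      continue;
    }
    double r0 = clearance(p, beads, L, r_bead, r_cap, nullptr);
    if (r0 < 0) { inside_bead[ip] = true; diam[ip] = NA_REAL; continue; }

    // multi-start directions: away from the three nearest beads
    std::vector<std::pair<double, int>> dists(m);
    for (int i = 0; i < m; ++i) {
      double b[3] = {beads(i, 0), beads(i, 1), beads(i, 2)};
      dists[i] = {mi_dist(p, b, L), i};
    }
    int nstart = std::min(3, m) + 2;
    std::partial_sort(dists.begin(), dists.begin() + std::min(3, m), dists.end());

    double best_r = r0, best_c[3] = {p[0], p[1], p[2]};
    for (int is = 0; is < nstart; ++is) {
      double c[3] = {p[0], p[1], p[2]};
      if (is > 0 && is < nstart - 1) {
        int bi = dists[is - 1].second;
        double b[3] = {beads(bi, 0), beads(bi, 1), beads(bi, 2)};
        double g[3]; mi_disp(p, b, L, g);
        double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
        if (gn > 1e-12) {
          // nudge start a quarter clearance away from that bead
          for (int k = 0; k < 3; ++k) c[k] = p[k] + 0.25 * r0 * g[k] / gn;
        }
      } else if (is == nstart - 1) {
        // far-corner start: the point of the nearest bead's periodic cell
        // diagonally opposite the bead (deep void candidate), pulled back
        // toward the probe until the probe-in-sphere constraint holds
        int bi = dists[0].second;
        double b[3] = {beads(bi, 0), beads(bi, 1), beads(bi, 2)};
        double g[3]; mi_disp(p, b, L, g);
        double corner[3];
        for (int k = 0; k < 3; ++k)
          corner[k] = b[k] + (g[k] >= 0 ? 0.5 : -0.5) * L[k];
        double dp[3]; mi_disp(corner, p, L, dp);
        double lo = 0.0, hi = 1.0;
        for (int b2 = 0; b2 < 30; ++b2) {
          double mid = 0.5 * (lo + hi);
          double cm[3];
          for (int k = 0; k < 3; ++k) cm[k] = p[k] + mid * dp[k];
          double rm = clearance(cm, beads, L, r_bead, r_cap, nullptr);
          double dm = mid * std::sqrt(dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2]);
          if (dm <= rm) lo = mid; else hi = mid;
        }
        for (int k = 0; k < 3; ++k) c[k] = p[k] + lo * dp[k];
      }
      double r = clearance(c, beads, L, r_bead, r_cap, nullptr);
      if (r < 0) continue;
      {
        double dp[3]; mi_disp(c, p, L, dp);
        double dpp = std::sqrt(dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2]);
        if (dpp > r) continue; // infeasible start
      }
      double step = 0.25 * std::max(r, 0.05);
      for (int it = 0; it < max_iter && step > tol * 0.01; ++it) {
        int nb = -1;
        clearance(c, beads, L, r_bead, r_cap, &nb);
        double g[3];
        double bpos[3] = {beads(nb, 0), beads(nb, 1), beads(nb, 2)};
        mi_disp(c, bpos, L, g);
        double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
        if (gn < 1e-12) break;
        double ct[3];
        for (int k = 0; k < 3; ++k) ct[k] = c[k] + step * g[k] / gn;
        // enforce the probe-in-sphere constraint: bisect back toward p
        double rt = clearance(ct, beads, L, r_bead, r_cap, nullptr);
        double dp[3]; mi_disp(ct, p, L, dp);
        double dpp = std::sqrt(dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2]);
        if (dpp > rt) {
          double lo = 0.0, hi = 1.0; // c(t) = p + t * (ct - p); t=0 feasible
          for (int b2 = 0; b2 < 30; ++b2) {
            double mid = 0.5 * (lo + hi);
            double cm[3];
            for (int k = 0; k < 3; ++k) cm[k] = p[k] + mid * dp[k];
            double rm = clearance(cm, beads, L, r_bead, r_cap, nullptr);
            double dm = mid * dpp;
            if (dm <= rm) lo = mid; else hi = mid;
          }
          for (int k = 0; k < 3; ++k) ct[k] = p[k] + lo * dp[k];
          rt = clearance(ct, beads, L, r_bead, r_cap, nullptr);
        }
        if (rt > r + tol * 0.01) {
          for (int k = 0; k < 3; ++k) c[k] = ct[k];
          if (rt - r < tol) { r = rt; break; }
          r = rt;
          step *= 1.3;
        } else {
          step *= 0.5;
        }
      }
      if (r > best_r) {
        best_r = r;
        for (int k = 0; k < 3; ++k) best_c[k] = c[k];
      }
    }
    diam[ip] = 2.0 * best_r;
    capped[ip] = (best_r >= r_cap - 1e-12);
    for (int k = 0; k < 3; ++k) centers(ip, k) = best_c[k];
  }
  return List::create(_["diameter"] = diam, _["center"] = centers,
                      _["inside_bead"] = inside_bead, _["capped"] = capped);
}
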