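#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};

inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

inline bool unit(V3& a) {
  double n = norm(a);
  if (n < 1e-14) return false;
  a.x /= n; a.y /= n; a.z /= n;
  return true;
}

inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// Signed solid-angle contribution of one segment pair to the Gauss double
// integral (Klenin & Langowski method 1a). Segments p1->p2 and p3->p4.
inline double segment_pair_omega(const V3& p1, const V3& p2,
                                 const V3& p3, const V3& p4) {
  V3 r13 = sub(p3, p1), r14 = sub(p4, p1);
  V3 r23 = sub(p3, p2), r24 = sub(p4, p2);
  V3 n1 = cross(r13, r14), n2 = cross(r14, r24);
  V3 n3 = cross(r24, r23), n4 = cross(r23, r13);
  if (!unit(n1) || !unit(n2) || !unit(n3) || !unit(n4)) return 0.0;
  double omega = std::asin(clamp1(dot(n1, n2))) + std::asin(clamp1(dot(n2, n3)))
               + std::asin(clamp1(dot(n3, n4))) + std::asin(clamp1(dot(n4, n1)));
  V3 r12 = sub(p2, p1), r34 = sub(p4, p3);
  double sgn = dot(cross(r34, r12), r13);
  if (sgn > 0) return omega;
  if (sgn < 0) return -omega;
  return 0.0;
}

inline V3 row(const NumericMatrix& m, int i) {
  return {m(i, 0), m(i, 1), m(i, 2)};
}

} // namespace

// Raw (unrounded) Gauss linking number of two closed polygons given as
// n x 3 vertex matrices (closure implied: last vertex connects to first).
// [[Rcpp::export(name = ".gauss_linking_raw_cpp")]]
double gauss_linking_raw_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    V3 a1 = row(A, i), a2 = row(A, (i + 1) % na);
    for (int j = 0; j < nb; ++j) {
      V3 b1 = row(B, j), b2 = row(B, (j + 1) % nb);
      total += segment_pair_omega(a1, a2, b1, b2);
    }
  }
  return total / (4.0 * M_PI);
}

// Minimum distance between the vertex sets of two polygons (cheap proximity
// guard used before evaluating Lk).
// [[Rcpp::export(name = ".min_vertex_distance_cpp")]]
double min_vertex_distance_cpp(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Crossing-sign linking number for one projection direction u (unit 3-vector).
// Returns twice the linking number (the signed crossing sum), or NA when the
// projection is degenerate (near-parallel segments at crossing scale or
// crossings too close to segment endpoints).
// [[Rcpp::export(name = ".crossing_sign_sum_cpp")]]
double crossing_sign_sum_cpp(NumericMatrix A, NumericMatrix B, NumericVector u) {
  V3 w = {u[0], u[1], u[2]};
  if (!unit(w)) return NA_REAL;
  // orthonormal basis (e1, e2, w)
  V3 t = (std::fabs(w.x) < 0.9) ? V3{1, 0, 0} : V3{0, 1, 0};
  V3 e1 = cross(w, t); unit(e1);
  V3 e2 = cross(w, e1);
  int na = A.nrow(), nb = B.nrow();
  const double eps = 1e-9;
  double sum = 0.0;
  for (int i = 0; i < na; ++i) {
    V3 a1 = row(A, i), a2 = row(A, (i + 1) % na);
    double ax1 = dot(a1, e1), ay1 = dot(a1, e2);
    double ax2 = dot(a2, e1), ay2 = dot(a2, e2);
    double adx = ax2 - ax1, ady = ay2 - ay1;
    for (int j = 0; j < nb; ++j) {
      V3 b1 = row(B, j), b2 = row(B, (j + 1) % nb);
      double bx1 = dot(b1, e1), by1 = dot(b1, e2);
      double bx2 = dot(b2, e1), by2 = dot(b2, e2);
      double bdx = bx2 - bx1, bdy = by2 - by1;
      double den = adx * bdy - ady * bdx;
      double scale = std::sqrt((adx * adx + ady * ady) * (bdx * bdx + bdy * bdy));
      if (scale < 1e-20) continue; // zero-length projected segment
      double s = ((bx1 - ax1) * bdy - (by1 - ay1) * bdx) / den;
      double tpar = ((bx1 - ax1) * ady - (by1 - ay1) * adx) / den;
      if (std::fabs(den) < 1e-12 * scale) {
        // near-parallel: only a problem if the segments actually overlap
        // in projection; flag degenerate conservatively when bounding boxes meet
        double alox = std::fmin(ax1, ax2) - eps, ahix = std::fmax(ax1, ax2) + eps;
        double aloy = std::fmin(ay1, ay2) - eps, ahiy = std::fmax(ay1, ay2) + eps;
        double blox = std::fmin(bx1, bx2), bhix = std::fmax(bx1, bx2);
        double bloy = std::fmin(by1, by2), bhiy = std::fmax(by1, by2);
        if (alox <= bhix && blox <= ahix && aloy <= bhiy && bloy <= ahiy)
          return NA_REAL;
        continue;
      }
      if (s <= -eps || s >= 1 + eps || tpar <= -eps || tpar >= 1 + eps) continue;
      if (s < eps || s > 1 - eps || tpar < eps || tpar > 1 - eps)
        return NA_REAL; // crossing at an endpoint: degenerate projection
      // 3-D points at the crossing
      V3 pa = {a1.x + s * (a2.x - a1.x), a1.y + s * (a2.y - a1.y), a1.z + s * (a2.z - a1.z)};
      V3 pb = {b1.x + tpar * (b2.x - b1.x), b1.y + tpar * (b2.y - b1.y), b1.z + tpar * (b2.z - b1.z)};
      V3 ta = sub(a2, a1), tb = sub(b2, b1);
      double sgn = dot(cross(ta, tb), sub(pa, pb));
      if (std::fabs(sgn) < 1e-12) return NA_REAL; // curves touch at crossing
      sum += (sgn > 0) ? 1.0 : -1.0;
    }
  }
  return sum;
}
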