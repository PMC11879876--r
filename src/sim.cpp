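// Rigid-body Langevin dynamics of patchy Y-shaped nanostars.
//
// Bodies are rigid assemblies of core beads (mass 1, WCA-repulsive,
// diameter sigma = 1) and massless terminal patch sites (Morse-attractive
// between compatible types). Friction and thermal noise act per core bead
// (free-draining), then reduce to a force/torque on the body, so the COM
// friction of a 7-bead star is 7 * Gamma. Integration is velocity Verlet
// with angular momentum in the world frame and quaternion drift split into
// two half-steps. An optional large tracer bead couples to core beads by a
// WCA potential with contact distance a + sigma/2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec {
  double x = 0, y = 0, z = 0;
};
inline Vec operator+(Vec a, Vec b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec operator-(Vec a, Vec b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec operator*(double s, Vec a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec a, Vec b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec cross(Vec a, Vec b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}

struct Quat {
  double w, x, y, z;
};

inline Quat qnorm(Quat q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  return {q.w / n, q.x / n, q.y / n, q.z / n};
}

// rotation matrix columns applied to v
inline Vec qrot(const Quat& q, Vec v) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  Vec r;
  r.x = (1 - 2 * (y * y + z * z)) * v.x + 2 * (x * y - w * z) * v.y + 2 * (x * z + w * y) * v.z;
  r.y = 2 * (x * y + w * z) * v.x + (1 - 2 * (x * x + z * z)) * v.y + 2 * (y * z - w * x) * v.z;
  r.z = 2 * (x * z - w * y) * v.x + 2 * (y * z + w * x) * v.y + (1 - 2 * (x * x + y * y)) * v.z;
  return r;
}

inline Vec qrot_inv(const Quat& q, Vec v) {
  Quat qc = {q.w, -q.x, -q.y, -q.z};
  return qrot(qc, v);
}

// dq/dt = (1/2) (0, omega_world) * q, integrated for time h then renormalized
inline Quat qdrift(Quat q, Vec w, double h) {
  Quat dq;
  dq.w = 0.5 * (-w.x * q.x - w.y * q.y - w.z * q.z);
  dq.x = 0.5 * (w.x * q.w + w.y * q.z - w.z * q.y);
  dq.y = 0.5 * (w.y * q.w + w.z * q.x - w.x * q.z);
  dq.z = 0.5 * (w.z * q.w + w.x * q.y - w.y * q.x);
  q.w += h * dq.w; q.x += h * dq.x; q.y += h * dq.y; q.z += h * dq.z;
  return qnorm(q);
}

struct Mat3 {
  double m[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
};

inline Vec matvec(const Mat3& A, Vec v) {
  return {A.m[0][0] * v.x + A.m[0][1] * v.y + A.m[0][2] * v.z,
          A.m[1][0] * v.x + A.m[1][1] * v.y + A.m[1][2] * v.z,
          A.m[2][0] * v.x + A.m[2][1] * v.y + A.m[2][2] * v.z};
}

Mat3 invert3(const Mat3& A) {
  const double (*a)[3] = A.m;
  double det = a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1])
             - a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0])
             + a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
  if (std::fabs(det) < 1e-14) stop("singular inertia tensor");
  Mat3 B;
  B.m[0][0] = (a[1][1] * a[2][2] - a[1][2] * a[2][1]) / det;
  B.m[0][1] = (a[0][2] * a[2][1] - a[0][1] * a[2][2]) / det;
  B.m[0][2] = (a[0][1] * a[1][2] - a[0][2] * a[1][1]) / det;
  B.m[1][0] = (a[1][2] * a[2][0] - a[1][0] * a[2][2]) / det;
  B.m[1][1] = (a[0][0] * a[2][2] - a[0][2] * a[2][0]) / det;
  B.m[1][2] = (a[0][2] * a[1][0] - a[0][0] * a[1][2]) / det;
  B.m[2][0] = (a[1][0] * a[2][1] - a[1][1] * a[2][0]) / det;
  B.m[2][1] = (a[0][1] * a[2][0] - a[0][0] * a[2][1]) / det;
  B.m[2][2] = (a[0][0] * a[1][1] - a[0][1] * a[1][0]) / det;
  return B;
}

// world-frame I^{-1} omega: omega = R I_b^{-1} R^T L
inline Vec omega_from_L(const Quat& q, const Mat3& Ibinv, Vec L) {
  Vec lb = qrot_inv(q, L);
  Vec wb = matvec(Ibinv, lb);
  return qrot(q, wb);
}

inline double mimg(double d, double L) { return d - L * std::round(d / L); }

struct ForceField {
  double eps, D0, alpha, r0, rc;      // WCA scale; Morse depth/width/minimum/cutoff
  double morse_shift;                 // value of unshifted Morse at rc
  double wca_cut = std::pow(2.0, 1.0 / 6.0);
};

// WCA pair force/energy at distance r with diameter sig (unit eps scaling
// applied by caller); returns dU/dr (negative magnitude convention: force on
// i along r_ij is -dU/dr * unit(r_ij))
inline void wca_pair(double r, double sig, double eps, double& u, double& dudr) {
  double sr = sig / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  u = 4.0 * eps * (sr12 - sr6) + eps;
  dudr = -4.0 * eps * (12.0 * sr12 - 6.0 * sr6) / r;
}

inline void morse_pair(double r, const ForceField& ff, double& u, double& dudr) {
  double e = std::exp(-ff.alpha * (r - ff.r0));
  double om = 1.0 - e;
  u = ff.D0 * (om * om - 1.0) - ff.morse_shift;
  dudr = 2.0 * ff.D0 * ff.alpha * e * om;
}

struct System {
  int N, nb, np;                  // bodies, beads per body, patches per body
  std::vector<Vec> body_beads, body_patches;   // body frame, COM at origin
  std::vector<int> type;          // 0 = A, 1 = B
  double Lbox[3];
  double mass;                    // body mass (= nb, bead mass 1)
  Mat3 Ibinv;
  // state
  std::vector<Vec> x, v, Lang;    // COM position (unwrapped), velocity, angular momentum
  std::vector<Quat> q;
  // tracer
  bool has_tracer = false;
  Vec tx, tv;
  double ta = 2.5, tmass = 125.0, tgamma = 5.0;
  // scratch: world-frame sites
  std::vector<Vec> site;          // N*(nb+np): beads first per body, then patches
  std::vector<Vec> site_f;
  Vec tracer_f;

  int sites_per_body() const { return nb + np; }

  void update_sites() {
    int spb = sites_per_body();
    for (int i = 0; i < N; ++i) {
      for (int b = 0; b < nb; ++b) site[i * spb + b] = x[i] + qrot(q[i], body_beads[b]);
      for (int p = 0; p < np; ++p) site[i * spb + nb + p] = x[i] + qrot(q[i], body_patches[p]);
    }
  }
};

struct ForceResult {
  double pe = 0;
  double virial[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
};

// pair interaction dispatch; si/sj are site indices within their bodies
inline void accumulate_pair(System& S, const ForceField& ff, bool attraction_on,
                            int bi, int bj, int ki, int kj, int gi, int gj,
                            ForceResult& out) {
  bool bead_i = ki < S.nb, bead_j = kj < S.nb;
  double cutoff;
  int kind; // 0 = WCA bead-bead, 1 = Morse patch-patch
  if (bead_i && bead_j) { cutoff = ff.wca_cut; kind = 0; }
  else if (!bead_i && !bead_j) {
    if (!attraction_on || S.type[bi] != S.type[bj]) return;
    cutoff = ff.rc; kind = 1;
  } else return;
  Vec d = S.site[gi] - S.site[gj];
  d.x = mimg(d.x, S.Lbox[0]); d.y = mimg(d.y, S.Lbox[1]); d.z = mimg(d.z, S.Lbox[2]);
  double r2 = dot(d, d);
  if (r2 >= cutoff * cutoff) return;
  double r = std::sqrt(r2);
  if (r < 1e-6) stop("overlapping sites at distance < 1e-6 sigma (force divergence)");
  double u, dudr;
  if (kind == 0) wca_pair(r, 1.0, ff.eps, u, dudr);
  else morse_pair(r, ff, u, dudr);
  out.pe += u;
  double fmag = -dudr / r; // force on i = fmag * d
  Vec f = fmag * d;
  S.site_f[gi] = S.site_f[gi] + f;
  S.site_f[gj] = S.site_f[gj] - f;
  double dv[3] = {d.x, d.y, d.z}, fv[3] = {f.x, f.y, f.z};
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) out.virial[a][b] += dv[a] * fv[b];
}

// full pairwise force pass (cell list over star sites; tracer brute force)
ForceResult compute_pair_forces(System& S, const ForceField& ff, bool attraction_on) {
  ForceResult out;
  int spb = S.sites_per_body();
  int M = S.N * spb;
  std::fill(S.site_f.begin(), S.site_f.end(), Vec{});
  S.tracer_f = Vec{};
  double cutoff = std::max(ff.wca_cut, ff.rc);

  int nc[3];
  for (int k = 0; k < 3; ++k) nc[k] = std::max(1, (int)std::floor(S.Lbox[k] / cutoff));
  bool use_cells = nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3 && M > 64;

  if (!use_cells) {
    for (int gi = 0; gi < M; ++gi) {
      int bi = gi / spb, ki = gi % spb;
      for (int gj = gi + 1; gj < M; ++gj) {
        int bj = gj / spb, kj = gj % spb;
        if (bi == bj) continue;
        accumulate_pair(S, ff, attraction_on, bi, bj, ki, kj, gi, gj, out);
      }
    }
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(M, -1);
    auto cell_of = [&](const Vec& p) {
      int cx = (int)std::floor(p.x / S.Lbox[0] * nc[0]); cx = ((cx % nc[0]) + nc[0]) % nc[0];
      int cy = (int)std::floor(p.y / S.Lbox[1] * nc[1]); cy = ((cy % nc[1]) + nc[1]) % nc[1];
      int cz = (int)std::floor(p.z / S.Lbox[2] * nc[2]); cz = ((cz % nc[2]) + nc[2]) % nc[2];
      return (cz * nc[1] + cy) * nc[0] + cx;
    };
    for (int g = 0; g < M; ++g) {
      int c = cell_of(S.site[g]);
      nxt[g] = head[c]; head[c] = g;
    }
    // half stencil: 13 forward neighbors + same cell
    static const int st[13][3] = {
      {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
      {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c = (cz * nc[1] + cy) * nc[0] + cx;
          // same cell
          for (int gi = head[c]; gi >= 0; gi = nxt[gi])
            for (int gj = nxt[gi]; gj >= 0; gj = nxt[gj]) {
              int bi = gi / spb, bj = gj / spb;
              if (bi == bj) continue;
              accumulate_pair(S, ff, attraction_on, bi, bj, gi % spb, gj % spb, gi, gj, out);
            }
          for (auto& sdx : st) {
            int ox = ((cx + sdx[0]) % nc[0] + nc[0]) % nc[0];
            int oy = ((cy + sdx[1]) % nc[1] + nc[1]) % nc[1];
            int oz = ((cz + sdx[2]) % nc[2] + nc[2]) % nc[2];
            int c2 = (oz * nc[1] + oy) * nc[0] + ox;
            if (c2 == c) continue;
            for (int gi = head[c]; gi >= 0; gi = nxt[gi])
              for (int gj = head[c2]; gj >= 0; gj = nxt[gj]) {
                int bi = gi / spb, bj = gj / spb;
                if (bi == bj) continue;
                accumulate_pair(S, ff, attraction_on, bi, bj, gi % spb, gj % spb, gi, gj, out);
              }
          }
        }
  }

  if (S.has_tracer) {
    double sigc = S.ta + 0.5;
    double cut_t = ff.wca_cut * sigc;
    for (int g = 0; g < M; ++g) {
      if (g % spb >= S.nb) continue; // beads only
      Vec d = S.tx - S.site[g];
      d.x = mimg(d.x, S.Lbox[0]); d.y = mimg(d.y, S.Lbox[1]); d.z = mimg(d.z, S.Lbox[2]);
      double r2 = dot(d, d);
      if (r2 >= cut_t * cut_t) continue;
      double r = std::sqrt(r2);
      if (r < 1e-6) stop("tracer overlaps bead");
      double u, dudr;
      wca_pair(r, sigc, ff.eps, u, dudr);
      out.pe += u;
      Vec f = (-dudr / r) * d;
      S.tracer_f = S.tracer_f + f;
      S.site_f[g] = S.site_f[g] - f;
      double dv[3] = {d.x, d.y, d.z}, fv[3] = {f.x, f.y, f.z};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) out.virial[a][b] += dv[a] * fv[b];
    }
  }
  return out;
}

// reduce site forces (plus optional per-bead Langevin) to body force/torque
void reduce_to_bodies(System& S, bool langevin, double gamma, double kT, double dt,
                      std::vector<Vec>& F, std::vector<Vec>& T) {
  int spb = S.sites_per_body();
  double noise = std::sqrt(2.0 * gamma * kT / dt);
  for (int i = 0; i < S.N; ++i) {
    Vec Fi{}, Ti{};
    Vec om = omega_from_L(S.q[i], S.Ibinv, S.Lang[i]);
    for (int k = 0; k < spb; ++k) {
      Vec f = S.site_f[i * spb + k];
      if (langevin && k < S.nb) {   // friction and noise on core beads only
        Vec rrel = S.site[i * spb + k] - S.x[i];
        Vec vb = S.v[i] + cross(om, rrel);
        f = f - gamma * vb;
        f.x += noise * norm_rand();
        f.y += noise * norm_rand();
        f.z += noise * norm_rand();
      }
      Fi = Fi + f;
      Vec rrel = S.site[i * spb + k] - S.x[i];
      Ti = Ti + cross(rrel, f);
    }
    F[i] = Fi; T[i] = Ti;
  }
}

System build_system(NumericMatrix centers, NumericMatrix quats, IntegerVector types,
                    NumericMatrix body_beads, NumericMatrix body_patches,
                    NumericVector box) {
  System S;
  S.N = centers.nrow();
  S.nb = body_beads.nrow();
  S.np = body_patches.nrow();
  for (int k = 0; k < 3; ++k) S.Lbox[k] = box[k];
  S.mass = S.nb; // bead mass 1

  // shift body frame so COM is at the origin; remember the shift
  Vec bcom{};
  for (int b = 0; b < S.nb; ++b)
    bcom = bcom + Vec{body_beads(b, 0), body_beads(b, 1), body_beads(b, 2)};
  bcom = (1.0 / S.nb) * bcom;
  for (int b = 0; b < S.nb; ++b)
    S.body_beads.push_back(Vec{body_beads(b, 0), body_beads(b, 1), body_beads(b, 2)} - bcom);
  for (int p = 0; p < S.np; ++p)
    S.body_patches.push_back(Vec{body_patches(p, 0), body_patches(p, 1), body_patches(p, 2)} - bcom);

  Mat3 Ib;
  for (int b = 0; b < S.nb; ++b) {
    Vec r = S.body_beads[b];
    double rr = dot(r, r);
    double rv[3] = {r.x, r.y, r.z};
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) Ib.m[a][c] += (a == c ? rr : 0.0) - rv[a] * rv[c];
  }
  S.Ibinv = invert3(Ib);

  S.x.resize(S.N); S.v.assign(S.N, Vec{}); S.Lang.assign(S.N, Vec{}); S.q.resize(S.N);
  S.type.assign(S.N, 0);
  for (int i = 0; i < S.N; ++i) {
    Quat qi = qnorm({quats(i, 0), quats(i, 1), quats(i, 2), quats(i, 3)});
    S.q[i] = qi;
    // input centers are body-origin positions; dynamics evolves the COM
    S.x[i] = Vec{centers(i, 0), centers(i, 1), centers(i, 2)} + qrot(qi, bcom);
    S.type[i] = types[i];
  }
  S.site.resize(S.N * S.sites_per_body());
  S.site_f.resize(S.N * S.sites_per_body());
  S.update_sites();
  return S;
}

ForceField build_ff(List ff_in) {
  ForceField ff;
  ff.eps = as<double>(ff_in["eps"]);
  ff.D0 = as<double>(ff_in["D0"]);
  ff.alpha = as<double>(ff_in["alpha"]);
  ff.r0 = as<double>(ff_in["r0"]);
  ff.rc = as<double>(ff_in["rc"]);
  double e = std::exp(-ff.alpha * (ff.rc - ff.r0));
  ff.morse_shift = ff.D0 * ((1.0 - e) * (1.0 - e) - 1.0);
  return ff;
}

Vec body_origin(const System& S, int i, const Vec& bcom_world_zero) {
  (void)bcom_world_zero;
  return S.x[i];
}

} // namespace

// Forces, energy and instantaneous pressure tensor of a static configuration.
// [[Rcpp::export(name = ".compute_forces_cpp")]]
List compute_forces_cpp(NumericMatrix centers, NumericMatrix quats, IntegerVector types,
                        NumericMatrix body_beads, NumericMatrix body_patches,
                        NumericVector box, List ff_in, bool attraction_on,
                        bool has_tracer, NumericVector tracer_pos, double tracer_a) {
  System S = build_system(centers, quats, types, body_beads, body_patches, box);
  ForceField ff = build_ff(ff_in);
  S.has_tracer = has_tracer;
  if (has_tracer) { S.ta = tracer_a; S.tx = {tracer_pos[0], tracer_pos[1], tracer_pos[2]}; }
  ForceResult fr = compute_pair_forces(S, ff, attraction_on);
  std::vector<Vec> F(S.N), T(S.N);
  reduce_to_bodies(S, false, 0, 0, 1, F, T);
  NumericMatrix Fm(S.N, 3), Tm(S.N, 3), P(3, 3);
  for (int i = 0; i < S.N; ++i) {
    Fm(i, 0) = F[i].x; Fm(i, 1) = F[i].y; Fm(i, 2) = F[i].z;
    Tm(i, 0) = T[i].x; Tm(i, 1) = T[i].y; Tm(i, 2) = T[i].z;
  }
  double V = box[0] * box[1] * box[2];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) P(a, b) = fr.virial[a][b] / V; // static: no kinetic part
  NumericVector tf(3);
  tf[0] = S.tracer_f.x; tf[1] = S.tracer_f.y; tf[2] = S.tracer_f.z;
  return List::create(_["energy"] = fr.pe, _["force"] = Fm, _["torque"] = Tm,
                      _["pressure"] = P, _["tracer_force"] = tf);
}

// One production/equilibration phase of rigid-body Langevin dynamics.
// Returns sampled frames (body-origin centers + quaternions), stress samples,
// energy samples, tracer track and the final state for chaining phases.
// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix centers, NumericMatrix quats, IntegerVector types,
                      NumericMatrix vel, NumericMatrix angmom,
                      NumericMatrix body_beads, NumericMatrix body_patches,
                      NumericVector box, List ff_in, bool attraction_on,
                      double dt, double gamma, double kT, bool thermostat,
                      int nsteps, int frame_every, int stress_every,
                      bool has_tracer, NumericVector tracer_state, double tracer_a,
                      double tracer_mass, double tracer_gamma, double t0,
                      double limit_disp) {
  System S = build_system(centers, quats, types, body_beads, body_patches, box);
  ForceField ff = build_ff(ff_in);
  for (int i = 0; i < S.N; ++i) {
    S.v[i] = {vel(i, 0), vel(i, 1), vel(i, 2)};
    S.Lang[i] = {angmom(i, 0), angmom(i, 1), angmom(i, 2)};
  }
  S.has_tracer = has_tracer;
  if (has_tracer) {
    S.ta = tracer_a; S.tmass = tracer_mass; S.tgamma = tracer_gamma;
    S.tx = {tracer_state[0], tracer_state[1], tracer_state[2]};
    S.tv = {tracer_state[3], tracer_state[4], tracer_state[5]};
  }

  // recover bcom (build_system shifted body frames; offset = mean of input beads)
  Vec bcom{};
  for (int b = 0; b < S.nb; ++b)
    bcom = bcom + Vec{body_beads(b, 0), body_beads(b, 1), body_beads(b, 2)};
  bcom = (1.0 / S.nb) * bcom;
  // centers passed in are body-origin; shift COM state accordingly was done in build_system

  int nframes = frame_every > 0 ? nsteps / frame_every : 0;
  int nstress = stress_every > 0 ? nsteps / stress_every : 0;
  NumericMatrix frame_centers(nframes * S.N, 3), frame_quats(nframes * S.N, 4);
  NumericVector frame_times(nframes);
  NumericMatrix tracer_track(std::max(nframes, 0), 3);
  NumericMatrix stress(nstress, 4);       // t, Pxy, Pxz, Pyz
  NumericMatrix energy(nstress, 3);       // t, PE, KE
  double V = box[0] * box[1] * box[2];

  std::vector<Vec> F(S.N), T(S.N);
  ForceResult fr = compute_pair_forces(S, ff, attraction_on);
  reduce_to_bodies(S, thermostat, gamma, kT, dt, F, T);
  Vec tF = S.tracer_f;
  if (S.has_tracer && thermostat) {
    double tn = std::sqrt(2.0 * S.tgamma * kT / dt);
    tF = tF - S.tgamma * S.tv;
    tF.x += tn * norm_rand(); tF.y += tn * norm_rand(); tF.z += tn * norm_rand();
  }

  int iframe = 0, istress = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // half kick
    for (int i = 0; i < S.N; ++i) {
      S.v[i] = S.v[i] + (0.5 * dt / S.mass) * F[i];
      S.Lang[i] = S.Lang[i] + 0.5 * dt * T[i];
    }
    if (S.has_tracer) S.tv = S.tv + (0.5 * dt / S.tmass) * tF;
    // drift (optionally displacement-limited: soft push-off for overlapping
    // initial states, as during equilibration after tracer insertion)
    for (int i = 0; i < S.N; ++i) {
      Vec dx = dt * S.v[i];
      if (limit_disp > 0) {
        double nd = std::sqrt(dot(dx, dx));
        if (nd > limit_disp) {
          dx = (limit_disp / nd) * dx;
          S.v[i] = (1.0 / dt) * dx;  // velocity follows the limited move
        }
      }
      S.x[i] = S.x[i] + dx;
      Vec om = omega_from_L(S.q[i], S.Ibinv, S.Lang[i]);
      if (limit_disp > 0) {
        double wn = std::sqrt(dot(om, om));
        if (wn * dt > limit_disp) {
          double f = limit_disp / (wn * dt);
          om = f * om;
          S.Lang[i] = f * S.Lang[i];
        }
      }
      S.q[i] = qdrift(S.q[i], om, 0.5 * dt);
      om = omega_from_L(S.q[i], S.Ibinv, S.Lang[i]);
      if (limit_disp > 0) {
        double wn = std::sqrt(dot(om, om));
        if (wn * dt > limit_disp) om = (limit_disp / (wn * dt)) * om;
      }
      S.q[i] = qdrift(S.q[i], om, 0.5 * dt);
    }
    if (S.has_tracer) {
      Vec dxt = dt * S.tv;
      if (limit_disp > 0) {
        double nd = std::sqrt(dot(dxt, dxt));
        if (nd > limit_disp) {
          dxt = (limit_disp / nd) * dxt;
          S.tv = (1.0 / dt) * dxt;
        }
      }
      S.tx = S.tx + dxt;
    }
    S.update_sites();
    // forces at new positions
    fr = compute_pair_forces(S, ff, attraction_on);
    reduce_to_bodies(S, thermostat, gamma, kT, dt, F, T);
    tF = S.tracer_f;
    if (S.has_tracer && thermostat) {
      double tn = std::sqrt(2.0 * S.tgamma * kT / dt);
      tF = tF - S.tgamma * S.tv;
      tF.x += tn * norm_rand(); tF.y += tn * norm_rand(); tF.z += tn * norm_rand();
    }
    // half kick
    for (int i = 0; i < S.N; ++i) {
      S.v[i] = S.v[i] + (0.5 * dt / S.mass) * F[i];
      S.Lang[i] = S.Lang[i] + 0.5 * dt * T[i];
    }
    if (S.has_tracer) S.tv = S.tv + (0.5 * dt / S.tmass) * tF;

    for (int i = 0; i < S.N; ++i)
      if (!std::isfinite(S.x[i].x + S.x[i].y + S.x[i].z))
        stop("non-finite coordinates at step %d: simulation blew up (reduce dt)", step);

    if (stress_every > 0 && step % stress_every == 0 && istress < nstress) {
      // kinetic part from per-bead velocities; virial from the last force pass
      double K[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      double ke = 0;
      int spb = S.sites_per_body();
      for (int i = 0; i < S.N; ++i) {
        Vec om = omega_from_L(S.q[i], S.Ibinv, S.Lang[i]);
        for (int b = 0; b < S.nb; ++b) {
          Vec rrel = S.site[i * spb + b] - S.x[i];
          Vec vb = S.v[i] + cross(om, rrel);
          double vv[3] = {vb.x, vb.y, vb.z};
          for (int a2 = 0; a2 < 3; ++a2)
            for (int b2 = 0; b2 < 3; ++b2) K[a2][b2] += vv[a2] * vv[b2];
          ke += 0.5 * dot(vb, vb);
        }
      }
      if (S.has_tracer) {
        double vv[3] = {S.tv.x, S.tv.y, S.tv.z};
        for (int a2 = 0; a2 < 3; ++a2)
          for (int b2 = 0; b2 < 3; ++b2) K[a2][b2] += S.tmass * vv[a2] * vv[b2];
        ke += 0.5 * S.tmass * dot(S.tv, S.tv);
      }
      stress(istress, 0) = t0 + step * dt;
      stress(istress, 1) = (K[0][1] + fr.virial[0][1]) / V;
      stress(istress, 2) = (K[0][2] + fr.virial[0][2]) / V;
      stress(istress, 3) = (K[1][2] + fr.virial[1][2]) / V;
      energy(istress, 0) = t0 + step * dt;
      energy(istress, 1) = fr.pe;
      energy(istress, 2) = ke;
      ++istress;
    }
    if (frame_every > 0 && step % frame_every == 0 && iframe < nframes) {
      for (int i = 0; i < S.N; ++i) {
        Vec xo = S.x[i] - qrot(S.q[i], bcom); // back to body-origin convention
        frame_centers(iframe * S.N + i, 0) = xo.x;
        frame_centers(iframe * S.N + i, 1) = xo.y;
        frame_centers(iframe * S.N + i, 2) = xo.z;
        frame_quats(iframe * S.N + i, 0) = S.q[i].w;
        frame_quats(iframe * S.N + i, 1) = S.q[i].x;
        frame_quats(iframe * S.N + i, 2) = S.q[i].y;
        frame_quats(iframe * S.N + i, 3) = S.q[i].z;
      }
      if (S.has_tracer) {
        tracer_track(iframe, 0) = S.tx.x;
        tracer_track(iframe, 1) = S.tx.y;
        tracer_track(iframe, 2) = S.tx.z;
      }
      frame_times[iframe] = t0 + step * dt;
      ++iframe;
    }
  }

  NumericMatrix xc(S.N, 3), qf(S.N, 4), vf(S.N, 3), lf(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    Vec xo = S.x[i] - qrot(S.q[i], bcom);
    xc(i, 0) = xo.x; xc(i, 1) = xo.y; xc(i, 2) = xo.z;
    qf(i, 0) = S.q[i].w; qf(i, 1) = S.q[i].x; qf(i, 2) = S.q[i].y; qf(i, 3) = S.q[i].z;
    vf(i, 0) = S.v[i].x; vf(i, 1) = S.v[i].y; vf(i, 2) = S.v[i].z;
    lf(i, 0) = S.Lang[i].x; lf(i, 1) = S.Lang[i].y; lf(i, 2) = S.Lang[i].z;
  }
  NumericVector tstate(6);
  if (S.has_tracer) {
    tstate[0] = S.tx.x; tstate[1] = S.tx.y; tstate[2] = S.tx.z;
    tstate[3] = S.tv.x; tstate[4] = S.tv.y; tstate[5] = S.tv.z;
  }
  return List::create(
    _["centers"] = xc, _["quats"] = qf, _["vel"] = vf, _["angmom"] = lf,
    _["frame_centers"] = frame_centers, _["frame_quats"] = frame_quats,
    _["frame_times"] = frame_times, _["tracer_track"] = tracer_track,
    _["stress"] = stress, _["energy"] = energy, _["tracer_state"] = tstate);
}
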