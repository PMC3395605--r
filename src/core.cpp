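// Compiled core: Hamiltonian evaluation (energies + analytic forces) and the
// BAOAB Langevin integrator for the two-bead structure-based model.
//
// Conventions: coordinates in Angstrom, energies in the reduced unit eps0,
// k_B = 1, bead mass = 1, time in tau = sqrt(m A^2 / eps0).  Indices arriving
// from R are 1-based and converted here.

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3 &o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3 &o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3 &o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3 &o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

inline long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long)i * n + j;
}

// All model terms, flattened to raw arrays for the integrator's inner loop.
struct Model {
  int n;
  NumericMatrix bonds;      // i j r0 K      (V = K/2 (r-r0)^2)
  NumericMatrix angles;     // i j k th0 K   (V = K/2 (th-th0)^2)
  NumericMatrix dihedrals;  // i j k l phi0 Kd  (SBM cosine, periods 1+3)
  NumericMatrix chirality;  // a b c d C0 Kc (V = Kc (C-C0)^2)
  NumericMatrix contacts;   // i j rnat eps  (V = eps[5(rn/r)^12 - 6(rn/r)^10])
  std::vector<int> qi;      // charged bead indices
  std::vector<double> qv;   // their charges
  std::unordered_set<long> excl;    // bonded/angle exclusions (DH + EV + contacts)
  std::unordered_set<long> ev_skip; // excl + native pairs (EV only)
  double dh_pref;           // K_coulomb * B / eps_r; <=0 disables electrostatics
  double kappa;
  double ev_eps, ev_sig2;   // EV: ev_eps * (sig/r)^12, shifted-truncated at 4 sig
  double ev_rc2, ev_shift;
  double wall_k, wall_r;    // flat-bottom spherical wall about origin; wall_r<=0 off
};

enum { C_BOND = 0, C_ANGLE, C_DIH, C_CHIR, C_CONTACT, C_EV, C_ELEC, C_WALL, NC };

inline Vec3 getv(const std::vector<double> &x, int i) {
  return Vec3(x[3 * i], x[3 * i + 1], x[3 * i + 2]);
}
inline void addf(std::vector<double> *f, int i, const Vec3 &v) {
  if (!f) return;
  (*f)[3 * i] += v.x; (*f)[3 * i + 1] += v.y; (*f)[3 * i + 2] += v.z;
}

// Evaluate all energy components; accumulate forces (-gradient) if f != NULL.
void eval_model(const Model &m, const std::vector<double> &x,
                std::vector<double> *f, double comp[NC]) {
  for (int c = 0; c < NC; ++c) comp[c] = 0.0;
  if (f) std::fill(f->begin(), f->end(), 0.0);

  // bonds
  for (int b = 0; b < m.bonds.nrow(); ++b) {
    int i = (int)m.bonds(b, 0) - 1, j = (int)m.bonds(b, 1) - 1;
    double r0 = m.bonds(b, 2), K = m.bonds(b, 3);
    Vec3 d = getv(x, i) - getv(x, j);
    double r = d.norm(), dr = r - r0;
    comp[C_BOND] += 0.5 * K * dr * dr;
    if (f && r > 1e-12) {
      Vec3 fi = d * (-K * dr / r);
      addf(f, i, fi); addf(f, j, fi * (-1.0));
    }
  }

  // angles
  for (int a = 0; a < m.angles.nrow(); ++a) {
    int i = (int)m.angles(a, 0) - 1, j = (int)m.angles(a, 1) - 1,
        k = (int)m.angles(a, 2) - 1;
    double th0 = m.angles(a, 3), K = m.angles(a, 4);
    Vec3 u = getv(x, i) - getv(x, j), v = getv(x, k) - getv(x, j);
    double nu = u.norm(), nv = v.norm();
    double ct = u.dot(v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct), dth = th - th0;
    comp[C_ANGLE] += 0.5 * K * dth * dth;
    if (f) {
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      // dth/dri etc.
      Vec3 dthi = (v * (1.0 / nv) - u * (ct / nu)) * (-1.0 / (nu * st));
      Vec3 dthk = (u * (1.0 / nu) - v * (ct / nv)) * (-1.0 / (nv * st));
      Vec3 fi = dthi * (-K * dth), fk = dthk * (-K * dth);
      addf(f, i, fi); addf(f, k, fk); addf(f, j, (fi + fk) * (-1.0));
    }
  }

  // backbone dihedrals (SBM: Kd[(1-cos(dphi)) + 0.5(1-cos(3 dphi))])
  for (int d = 0; d < m.dihedrals.nrow(); ++d) {
    int i = (int)m.dihedrals(d, 0) - 1, j = (int)m.dihedrals(d, 1) - 1,
        k = (int)m.dihedrals(d, 2) - 1, l = (int)m.dihedrals(d, 3) - 1;
    double phi0 = m.dihedrals(d, 4), Kd = m.dihedrals(d, 5);
    Vec3 b1 = getv(x, j) - getv(x, i), b2 = getv(x, k) - getv(x, j),
         b3 = getv(x, l) - getv(x, k);
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double nb2 = b2.norm();
    double phi = std::atan2(n1.cross(n2).dot(b2) / nb2, n1.dot(n2));
    double dphi = phi - phi0;
    comp[C_DIH] += Kd * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
    if (f) {
      double dV = Kd * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
      double n1sq = n1.dot(n1), n2sq = n2.dot(n2);
      if (n1sq > 1e-12 && n2sq > 1e-12) {
        Vec3 dpi = n1 * (-nb2 / n1sq);
        Vec3 dpl = n2 * (nb2 / n2sq);
        double c12 = b1.dot(b2) / (nb2 * nb2), c32 = b3.dot(b2) / (nb2 * nb2);
        Vec3 dpj = dpi * (-(1.0 + c12)) + dpl * c32;
        Vec3 dpk = dpi * c12 - dpl * (1.0 + c32);
        addf(f, i, dpi * (-dV)); addf(f, j, dpj * (-dV));
        addf(f, k, dpk * (-dV)); addf(f, l, dpl * (-dV));
      }
    }
  }

  // side-chain chirality: C = (v1 x v2).v3 / (|v1||v2||v3|), V = Kc (C - C0)^2
  for (int c = 0; c < m.chirality.nrow(); ++c) {
    int a = (int)m.chirality(c, 0) - 1, b = (int)m.chirality(c, 1) - 1,
        cc = (int)m.chirality(c, 2) - 1, d = (int)m.chirality(c, 3) - 1;
    double C0 = m.chirality(c, 4), Kc = m.chirality(c, 5);
    Vec3 v1 = getv(x, b) - getv(x, a), v2 = getv(x, cc) - getv(x, b),
         v3 = getv(x, d) - getv(x, b);
    double N = v1.cross(v2).dot(v3);
    double n1 = v1.norm(), n2 = v2.norm(), n3 = v3.norm();
    double D = n1 * n2 * n3;
    if (D < 1e-12) continue;
    double C = N / D, dC = C - C0;
    comp[C_CHIR] += Kc * dC * dC;
    if (f) {
      // dC/dv = (dN/dv - C dD/dv)/D
      Vec3 g1 = (v2.cross(v3) - v1 * (C * n2 * n3 / n1)) * (1.0 / D);
      Vec3 g2 = (v3.cross(v1) - v2 * (C * n1 * n3 / n2)) * (1.0 / D);
      Vec3 g3 = (v1.cross(v2) - v3 * (C * n1 * n2 / n3)) * (1.0 / D);
      double s = -2.0 * Kc * dC;  // force = -dV/dC * dC/dr
      addf(f, a, g1 * (-s));
      addf(f, b, (g1 - g2 - g3) * s);
      addf(f, cc, g2 * s);
      addf(f, d, g3 * s);
    }
  }

  // native contacts (12-10)
  for (int c = 0; c < m.contacts.nrow(); ++c) {
    int i = (int)m.contacts(c, 0) - 1, j = (int)m.contacts(c, 1) - 1;
    double rn = m.contacts(c, 2), eps = m.contacts(c, 3);
    Vec3 d = getv(x, i) - getv(x, j);
    double r = d.norm();
    double s10 = std::pow(rn / r, 10), s12 = s10 * (rn / r) * (rn / r);
    comp[C_CONTACT] += eps * (5.0 * s12 - 6.0 * s10);
    if (f) {
      double dVdr = (60.0 * eps / r) * (s10 - s12);
      Vec3 fi = d * (-dVdr / r);
      addf(f, i, fi); addf(f, j, fi * (-1.0));
    }
  }

  // excluded volume over all non-native, non-excluded pairs
  if (m.ev_eps > 0) {
    for (int i = 0; i < m.n - 1; ++i) {
      Vec3 xi = getv(x, i);
      for (int j = i + 1; j < m.n; ++j) {
        Vec3 d = xi - getv(x, j);
        double r2 = d.dot(d);
        if (r2 >= m.ev_rc2) continue;
        if (m.ev_skip.count(pair_key(i, j, m.n))) continue;
        double s2 = m.ev_sig2 / r2, s4 = s2 * s2;
        double s12 = s4 * s4 * s4;
        comp[C_EV] += m.ev_eps * s12 - m.ev_shift;
        if (f) {
          double dVdr_over_r = -12.0 * m.ev_eps * s12 / r2;
          Vec3 fi = d * (-dVdr_over_r);
          addf(f, i, fi); addf(f, j, fi * (-1.0));
        }
      }
    }
  }

  // Debye-Hueckel over all charged pairs (native and non-native alike)
  if (m.dh_pref > 0 && m.qi.size() > 1) {
    for (size_t a = 0; a + 1 < m.qi.size(); ++a) {
      int i = m.qi[a];
      Vec3 xi = getv(x, i);
      for (size_t b = a + 1; b < m.qi.size(); ++b) {
        int j = m.qi[b];
        if (m.excl.count(pair_key(i, j, m.n))) continue;
        Vec3 d = xi - getv(x, j);
        double r = d.norm();
        if (r < 0.01) stop("overlapping charged beads (r < 0.01 A)");
        double qq = m.qv[a] * m.qv[b];
        double e = m.dh_pref * qq * std::exp(-m.kappa * r) / r;
        comp[C_ELEC] += e;
        if (f) {
          double dVdr = -e * (m.kappa + 1.0 / r);
          Vec3 fi = d * (-dVdr / r);
          addf(f, i, fi); addf(f, j, fi * (-1.0));
        }
      }
    }
  }

  // soft spherical wall (keeps dissociated chains re-encounterable)
  if (m.wall_r > 0) {
    for (int i = 0; i < m.n; ++i) {
      Vec3 xi = getv(x, i);
      double r = xi.norm();
      if (r > m.wall_r) {
        double dr = r - m.wall_r;
        comp[C_WALL] += 0.5 * m.wall_k * dr * dr;
        if (f) addf(f, i, xi * (-m.wall_k * dr / r));
      }
    }
  }
}

Model build_model(int n, List terms) {
  Model m;
  m.n = n;
  m.bonds = as<NumericMatrix>(terms["bonds"]);
  m.angles = as<NumericMatrix>(terms["angles"]);
  m.dihedrals = as<NumericMatrix>(terms["dihedrals"]);
  m.chirality = as<NumericMatrix>(terms["chirality"]);
  m.contacts = as<NumericMatrix>(terms["contacts"]);
  NumericVector q = terms["charges"];
  for (int i = 0; i < n; ++i)
    if (q[i] != 0) { m.qi.push_back(i); m.qv.push_back(q[i]); }
  IntegerMatrix excl = terms["exclusions"];  // 1-based pairs
  for (int r = 0; r < excl.nrow(); ++r)
    m.excl.insert(pair_key(excl(r, 0) - 1, excl(r, 1) - 1, n));
  m.ev_skip = m.excl;
  for (int c = 0; c < m.contacts.nrow(); ++c)
    m.ev_skip.insert(pair_key((int)m.contacts(c, 0) - 1,
                              (int)m.contacts(c, 1) - 1, n));
  m.dh_pref = as<double>(terms["dh_pref"]);
  m.kappa = as<double>(terms["kappa"]);
  m.ev_eps = as<double>(terms["ev_eps"]);
  double sig = as<double>(terms["ev_sigma"]);
  m.ev_sig2 = sig * sig;
  double rc = 4.0 * sig;  // shifted truncation; discontinuity ~1e-7 eps0
  m.ev_rc2 = rc * rc;
  m.ev_shift = m.ev_eps / (65536.0 * 256.0);  // (1/4)^12
  m.wall_k = as<double>(terms["wall_k"]);
  m.wall_r = as<double>(terms["wall_r"]);
  return m;
}

std::vector<double> flatten(const NumericMatrix &xyz) {
  int n = xyz.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = xyz(i, 0); x[3 * i + 1] = xyz(i, 1); x[3 * i + 2] = xyz(i, 2);
  }
  return x;
}

CharacterVector comp_names() {
  return CharacterVector::create("bond", "angle", "dihedral", "chirality",
                                 "native_contact", "excluded_volume",
                                 "electrostatic", "wall");
}

}  // namespace

// [[Rcpp::export]]
List cpp_eval(NumericMatrix xyz, List terms, bool want_forces) {
  int n = xyz.nrow();
  Model m = build_model(n, terms);
  std::vector<double> x = flatten(xyz);
  double comp[NC];
  if (want_forces) {
    std::vector<double> f(3 * n);
    eval_model(m, x, &f, comp);
    NumericMatrix F(n, 3);
    for (int i = 0; i < n; ++i) {
      F(i, 0) = f[3 * i]; F(i, 1) = f[3 * i + 1]; F(i, 2) = f[3 * i + 2];
    }
    NumericVector cv(comp, comp + NC);
    cv.attr("names") = comp_names();
    return List::create(_["components"] = cv, _["forces"] = F);
  }
  eval_model(m, x, NULL, comp);
  NumericVector cv(comp, comp + NC);
  cv.attr("names") = comp_names();
  return List::create(_["components"] = cv);
}

// BAOAB Langevin (gamma > 0) or velocity Verlet (gamma <= 0, NVE).
// Optional early stop: fraction of `stop_rows` contacts formed (r < tol*rnat)
// >= stop_q for stop_hold consecutive saved frames.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix xyz0, NumericMatrix vel0, List terms,
                  double dt, double gamma, double kT,
                  double n_steps_d, int save_interval,
                  IntegerVector stop_rows, double stop_q, int stop_hold,
                  double stop_tol, bool save_velocities) {
  int n = xyz0.nrow();
  long n_steps = (long)n_steps_d;
  Model m = build_model(n, terms);
  std::vector<double> x = flatten(xyz0), v = flatten(vel0), f(3 * n);
  double comp[NC];
  eval_model(m, x, &f, comp);

  long n_save = n_steps / save_interval + 1;
  NumericMatrix frames(n_save, 3 * n);
  NumericMatrix energies(n_save, NC);
  NumericMatrix vels(save_velocities ? n_save : 1, save_velocities ? 3 * n : 1);
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(kT * (1.0 - c1 * c1)) : 0.0;

  double tkin_sum = 0.0;
  long tkin_n = 0, saved = 0, hold = 0, stop_step = -1;
  std::string stop_reason = "max_steps";

  // save frame 0
  for (int d = 0; d < 3 * n; ++d) frames(0, d) = x[d];
  for (int c = 0; c < NC; ++c) energies(0, c) = comp[c];
  if (save_velocities) for (int d = 0; d < 3 * n; ++d) vels(0, d) = v[d];
  saved = 1;

  for (long step = 1; step <= n_steps; ++step) {
    if (gamma > 0) {  // BAOAB
      for (int d = 0; d < 3 * n; ++d) v[d] += 0.5 * dt * f[d];
      for (int d = 0; d < 3 * n; ++d) x[d] += 0.5 * dt * v[d];
      for (int d = 0; d < 3 * n; ++d) v[d] = c1 * v[d] + c2 * norm_rand();
      for (int d = 0; d < 3 * n; ++d) x[d] += 0.5 * dt * v[d];
      eval_model(m, x, &f, comp);
      for (int d = 0; d < 3 * n; ++d) v[d] += 0.5 * dt * f[d];
    } else {  // velocity Verlet (NVE)
      for (int d = 0; d < 3 * n; ++d) v[d] += 0.5 * dt * f[d];
      for (int d = 0; d < 3 * n; ++d) x[d] += dt * v[d];
      eval_model(m, x, &f, comp);
      for (int d = 0; d < 3 * n; ++d) v[d] += 0.5 * dt * f[d];
    }

    if (step % save_interval == 0) {
      double ke = 0.0;
      for (int d = 0; d < 3 * n; ++d) ke += v[d] * v[d];
      tkin_sum += ke / (3.0 * n);
      tkin_n++;
      double etot = 0.0;
      for (int c = 0; c < NC; ++c) etot += comp[c];
      if (!std::isfinite(etot) || std::fabs(etot) > 1e8) {
        stop_reason = "blowup";
        stop_step = step;
        break;
      }
      for (int d = 0; d < 3 * n; ++d) frames(saved, d) = x[d];
      for (int c = 0; c < NC; ++c) energies(saved, c) = comp[c];
      if (save_velocities) for (int d = 0; d < 3 * n; ++d) vels(saved, d) = v[d];
      saved++;
      if (stop_rows.size() > 0) {
        int formed = 0;
        for (int s = 0; s < stop_rows.size(); ++s) {
          int row = stop_rows[s] - 1;
          int i = (int)m.contacts(row, 0) - 1, j = (int)m.contacts(row, 1) - 1;
          Vec3 d = getv(x, i) - getv(x, j);
          if (d.norm() < stop_tol * m.contacts(row, 2)) formed++;
        }
        double q = (double)formed / stop_rows.size();
        hold = (q >= stop_q) ? hold + 1 : 0;
        if (hold >= stop_hold) {
          stop_reason = "bound";
          stop_step = step;
          break;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix Fr(saved, 3 * n), En(saved, NC);
  for (long r = 0; r < saved; ++r) {
    for (int d = 0; d < 3 * n; ++d) Fr(r, d) = frames(r, d);
    for (int c = 0; c < NC; ++c) En(r, c) = energies(r, c);
  }
  colnames(En) = comp_names();
  NumericMatrix Vfinal(n, 3);
  for (int i = 0; i < n; ++i) {
    Vfinal(i, 0) = v[3 * i]; Vfinal(i, 1) = v[3 * i + 1]; Vfinal(i, 2) = v[3 * i + 2];
  }
  List out = List::create(
      _["frames"] = Fr, _["energies"] = En, _["v_final"] = Vfinal,
      _["kinetic_temperature"] = (tkin_n > 0) ? tkin_sum / tkin_n : NA_REAL,
      _["stop_reason"] = stop_reason, _["stop_step"] = (double)stop_step,
      _["n_saved"] = (double)saved);
  if (save_velocities) {
    NumericMatrix Vs(saved, 3 * n);
    for (long r = 0; r < saved; ++r)
      for (int d = 0; d < 3 * n; ++d) Vs(r, d) = vels(r, d);
    out["velocities"] = Vs;
  }
  return out;
}
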