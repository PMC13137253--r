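// Metropolis Monte Carlo core for a rigid united-atom solute in a neutral
// Lennard-Jones solvent, with soft-core alchemical cross interactions.
// Units: kJ/mol, nm. All randomness comes from R's RNG (unif_rand /
// norm_rand), so set.seed() in R fully determines a run.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// positions live in [0, box), so pair differences are in (-box, box) and a
// branch beats round(); general callers still get the wrapped result
static inline double min_img(double d, double box) {
  double hb = 0.5 * box;
  if (d > hb) {
    d -= box;
    if (d > hb) d -= box * std::floor(d / box + 0.5);
  } else if (d < -hb) {
    d += box;
    if (d < -hb) d -= box * std::floor(d / box + 0.5);
  }
  return d;
}

// soft-core LJ: lam^n * 4 eps [ t^-2 - t^-1 ], t = alpha (1-lam)^2 + (r/sig)^6
static inline double ipow(double x, int n) {
  double out = 1.0;
  for (int i = 0; i < n; ++i) out *= x;
  return out;
}

static inline double sc_pair(double r2, double eps, double sig, double lam,
                             double alpha, int nexp) {
  if (lam <= 0.0 || eps == 0.0) return 0.0;
  double sig2 = sig * sig;
  double sr6 = (r2 * r2 * r2) / (sig2 * sig2 * sig2);
  double t = alpha * (1.0 - lam) * (1.0 - lam) + sr6;
  if (t < 1e-300) return 1e12;  // lam = 1 hard-core contact
  double inv = 1.0 / t;
  return ipow(lam, nexp) * 4.0 * eps * (inv * inv - inv);
}

static inline double lj_pair(double r2, double eps, double sig) {
  if (eps == 0.0) return 0.0;
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6);
}

struct System {
  std::vector<double> sx, sy, sz;      // solvent
  std::vector<double> ux, uy, uz;      // solute sites (absolute coords)
  std::vector<double> eps_x, sig_x;    // cross parameters per solute site
  double eps_ss, sig_ss;
  double box;
  double rc_x, rc_ss;
  bool shift_x, shift_ss;
  double alpha; int nexp;

  int n() const { return (int)sx.size(); }
  int m() const { return (int)ux.size(); }

  double u_rc_cross(int k, double lam) const {
    return shift_x ? sc_pair(rc_x * rc_x, eps_x[k], sig_x[k], lam, alpha, nexp)
                   : 0.0;
  }
  double u_rc_ss() const {
    return shift_ss ? lj_pair(rc_ss * rc_ss, eps_ss, sig_ss) : 0.0;
  }

  // cross energy of solvent particle j at coupling lam
  double cross_one(double x, double y, double z, double lam) const {
    double e = 0.0, rc2 = rc_x * rc_x;
    for (int k = 0; k < m(); ++k) {
      double dx = min_img(x - ux[k], box);
      double dy = min_img(y - uy[k], box);
      double dz = min_img(z - uz[k], box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2)
        e += sc_pair(r2, eps_x[k], sig_x[k], lam, alpha, nexp) -
             u_rc_cross(k, lam);
    }
    return e;
  }

  double cross_total(double lam) const {
    double e = 0.0;
    for (int j = 0; j < n(); ++j) e += cross_one(sx[j], sy[j], sz[j], lam);
    return e;
  }

  // solvent-solvent energy of particle j against all others
  double ss_one(int j, double x, double y, double z) const {
    double e = 0.0, rc2 = rc_ss * rc_ss, shift = u_rc_ss();
    for (int i = 0; i < n(); ++i) {
      if (i == j) continue;
      double dx = min_img(x - sx[i], box);
      double dy = min_img(y - sy[i], box);
      double dz = min_img(z - sz[i], box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2) e += lj_pair(r2, eps_ss, sig_ss) - shift;
    }
    return e;
  }

  double ss_total() const {
    double e = 0.0, rc2 = rc_ss * rc_ss, shift = u_rc_ss();
    for (int i = 0; i < n(); ++i)
      for (int j = i + 1; j < n(); ++j) {
        double dx = min_img(sx[i] - sx[j], box);
        double dy = min_img(sy[i] - sy[j], box);
        double dz = min_img(sz[i] - sz[j], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) e += lj_pair(r2, eps_ss, sig_ss) - shift;
      }
    return e;
  }

  void wrap(int j) {
    sx[j] -= box * std::floor(sx[j] / box);
    sy[j] -= box * std::floor(sy[j] / box);
    sz[j] -= box * std::floor(sz[j] / box);
  }
};

static System make_system(NumericMatrix solv, NumericMatrix solu,
                          NumericVector eps_x, NumericVector sig_x,
                          double eps_ss, double sig_ss, double box,
                          double rc_x, double rc_ss, bool shift_x,
                          bool shift_ss, double alpha, int nexp) {
  System s;
  int n = solv.nrow(), m = solu.nrow();
  s.sx.resize(n); s.sy.resize(n); s.sz.resize(n);
  for (int j = 0; j < n; ++j) {
    s.sx[j] = solv(j, 0); s.sy[j] = solv(j, 1); s.sz[j] = solv(j, 2);
  }
  s.ux.resize(m); s.uy.resize(m); s.uz.resize(m);
  s.eps_x.resize(m); s.sig_x.resize(m);
  for (int k = 0; k < m; ++k) {
    s.ux[k] = solu(k, 0); s.uy[k] = solu(k, 1); s.uz[k] = solu(k, 2);
    s.eps_x[k] = eps_x[k]; s.sig_x[k] = sig_x[k];
  }
  s.eps_ss = eps_ss; s.sig_ss = sig_ss; s.box = box;
  s.rc_x = rc_x; s.rc_ss = rc_ss; s.shift_x = shift_x; s.shift_ss = shift_ss;
  s.alpha = alpha; s.nexp = nexp;
  return s;
}

// [[Rcpp::export]]
double cpp_cross_energy(NumericMatrix solv, NumericMatrix solu,
                        NumericVector eps_x, NumericVector sig_x, double box,
                        double lam, double alpha, int nexp, double rc_x,
                        bool shift_x) {
  System s = make_system(solv, solu, eps_x, sig_x, 0.0, 1.0, box, rc_x, 1.0,
                         shift_x, false, alpha, nexp);
  return s.cross_total(lam);
}

// [[Rcpp::export]]
double cpp_solvent_energy(NumericMatrix solv, double eps_ss, double sig_ss,
                          double box, double rc_ss, bool shift_ss) {
  NumericMatrix dummy(1, 3);
  NumericVector e0(1), s1(1); s1[0] = 1.0;
  System s = make_system(solv, dummy, e0, s1, eps_ss, sig_ss, box, 1.0, rc_ss,
                         false, shift_ss, 0.5, 2);
  return s.ss_total();
}

// One lambda window: Metropolis sweeps at coupling `lam`, recording
// dU = U_cross(lam_other) - U_cross(lam) and V at sampled configurations.
// [[Rcpp::export]]
List cpp_run_window(NumericMatrix solv, NumericMatrix solu,
                    NumericVector eps_x, NumericVector sig_x, double eps_ss,
                    double sig_ss, double box, double rc_x, double rc_ss,
                    bool shift_x, bool shift_ss, double lam, double lam_other,
                    double alpha, int nexp, double kT, int n_sweeps,
                    int n_burnin, int sample_every, double max_disp,
                    bool record_frames, int frame_every, bool npt,
                    double pressure, double max_dlnV, int vol_every) {
  System s = make_system(solv, solu, eps_x, sig_x, eps_ss, sig_ss, box, rc_x,
                         rc_ss, shift_x, shift_ss, alpha, nexp);
  int n = s.n();
  double beta = 1.0 / kT;
  double U_run = s.ss_total() + s.cross_total(lam);  // running total energy
  long n_acc = 0, n_try = 0;
  std::vector<double> dU_out, V_out;
  List frames;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      int j = (int)std::floor(unif_rand() * n);
      if (j == n) j = n - 1;
      double ox = s.sx[j], oy = s.sy[j], oz = s.sz[j];
      double e_old = s.ss_one(j, ox, oy, oz) + s.cross_one(ox, oy, oz, lam);
      double nx = ox + (unif_rand() - 0.5) * 2.0 * max_disp;
      double ny = oy + (unif_rand() - 0.5) * 2.0 * max_disp;
      double nz = oz + (unif_rand() - 0.5) * 2.0 * max_disp;
      double e_new = s.ss_one(j, nx, ny, nz) + s.cross_one(nx, ny, nz, lam);
      double dE = e_new - e_old;
      ++n_try;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        s.sx[j] = nx; s.sy[j] = ny; s.sz[j] = nz;
        s.wrap(j);
        U_run += dE;
        ++n_acc;
      }
    }
    if (npt && vol_every > 0 && sweep % vol_every == 0) {
      double V_old = s.box * s.box * s.box;
      double lnV_new = std::log(V_old) + (unif_rand() - 0.5) * 2.0 * max_dlnV;
      double V_new = std::exp(lnV_new);
      double box_new = std::cbrt(V_new);
      double rc_need = std::max(s.rc_x, s.rc_ss);
      if (box_new > 2.0 * rc_need) {
        System trial = s;
        double f = box_new / s.box;
        for (int j = 0; j < n; ++j) {
          trial.sx[j] = s.sx[j] * f; trial.sy[j] = s.sy[j] * f;
          trial.sz[j] = s.sz[j] * f;
        }
        // rigid solute: translate its centroid with the box, keep geometry
        double cx = 0, cy = 0, cz = 0;
        for (int k = 0; k < s.m(); ++k) { cx += s.ux[k]; cy += s.uy[k]; cz += s.uz[k]; }
        cx /= s.m(); cy /= s.m(); cz /= s.m();
        for (int k = 0; k < s.m(); ++k) {
          trial.ux[k] = s.ux[k] + cx * (f - 1.0);
          trial.uy[k] = s.uy[k] + cy * (f - 1.0);
          trial.uz[k] = s.uz[k] + cz * (f - 1.0);
        }
        trial.box = box_new;
        double U_new = trial.ss_total() + trial.cross_total(lam);
        double U_old = s.ss_total() + s.cross_total(lam);
        double arg = -beta * (U_new - U_old) - beta * pressure * (V_new - V_old) +
                     (n + 1) * (lnV_new - std::log(V_old));
        if (arg >= 0.0 || unif_rand() < std::exp(arg)) {
          s = trial;
          U_run += U_new - U_old;
        }
      }
    }
    if (sweep > n_burnin) {
      if (sample_every > 0 && (sweep - n_burnin) % sample_every == 0) {
        double Ui = s.cross_total(lam);
        double Uj = s.cross_total(lam_other);
        dU_out.push_back(Uj - Ui);
        V_out.push_back(s.box * s.box * s.box);
      }
      if (record_frames && frame_every > 0 &&
          (sweep - n_burnin) % frame_every == 0) {
        NumericMatrix fr(n, 3);
        for (int j = 0; j < n; ++j) {
          fr(j, 0) = s.sx[j]; fr(j, 1) = s.sy[j]; fr(j, 2) = s.sz[j];
        }
        frames.push_back(fr);
      }
    }
  }

  // exact energy bookkeeping check: running total vs full recomputation
  double drift = std::abs((s.ss_total() + s.cross_total(lam)) - U_run);
  NumericMatrix out_solv(n, 3);
  for (int j = 0; j < n; ++j) {
    out_solv(j, 0) = s.sx[j]; out_solv(j, 1) = s.sy[j]; out_solv(j, 2) = s.sz[j];
  }
  NumericMatrix out_solu(s.m(), 3);
  for (int k = 0; k < s.m(); ++k) {
    out_solu(k, 0) = s.ux[k]; out_solu(k, 1) = s.uy[k]; out_solu(k, 2) = s.uz[k];
  }
  return List::create(
      _["solvent"] = out_solv, _["solute"] = out_solu, _["box"] = s.box,
      _["dU"] = NumericVector(dU_out.begin(), dU_out.end()),
      _["V"] = NumericVector(V_out.begin(), V_out.end()),
      _["acceptance"] = n_try > 0 ? (double)n_acc / (double)n_try : NA_REAL,
      _["energy_drift"] = drift, _["frames"] = frames);
}

// Widom insertion energies: random positions and orientations of the solute
// template (coordinates relative to its centroid) in the solvent box.
// [[Rcpp::export]]
NumericVector cpp_insertion_energies(NumericMatrix solv, NumericMatrix solu_rel,
                                     NumericVector eps_x, NumericVector sig_x,
                                     double box, double rc_x, bool shift_x,
                                     double alpha, int nexp, int n_ins) {
  System s = make_system(solv, solu_rel, eps_x, sig_x, 0.0, 1.0, box, rc_x,
                         1.0, shift_x, false, alpha, nexp);
  int m = solu_rel.nrow();
  NumericVector out(n_ins);
  for (int t = 0; t < n_ins; ++t) {
    double px = unif_rand() * box, py = unif_rand() * box, pz = unif_rand() * box;
    // uniform random rotation from a normalised quaternion
    double q0 = norm_rand(), q1 = norm_rand(), q2 = norm_rand(), q3 = norm_rand();
    double qn = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
    q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
    double R[3][3] = {
        {1 - 2 * (q2 * q2 + q3 * q3), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2)},
        {2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1 * q1 + q3 * q3), 2 * (q2 * q3 - q0 * q1)},
        {2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1 * q1 + q2 * q2)}};
    double e = 0.0, rc2 = rc_x * rc_x;
    for (int k = 0; k < m; ++k) {
      double rx = solu_rel(k, 0), ry = solu_rel(k, 1), rz = solu_rel(k, 2);
      double xk = px + R[0][0] * rx + R[0][1] * ry + R[0][2] * rz;
      double yk = py + R[1][0] * rx + R[1][1] * ry + R[1][2] * rz;
      double zk = pz + R[2][0] * rx + R[2][1] * ry + R[2][2] * rz;
      for (int j = 0; j < s.n(); ++j) {
        double dx = min_img(xk - s.sx[j], box);
        double dy = min_img(yk - s.sy[j], box);
        double dz = min_img(zk - s.sz[j], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2)
          e += sc_pair(r2, eps_x[k], sig_x[k], 1.0, alpha, nexp) -
               (shift_x ? sc_pair(rc2, eps_x[k], sig_x[k], 1.0, alpha, nexp)
                        : 0.0);
      }
    }
    out[t] = e;
  }
  return out;
}
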