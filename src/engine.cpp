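// Langevin (BAOAB) integrator for toy receptor-ligand systems with
// harmonic CV walls, a sigmoidal funnel restraint and well-tempered
// metadynamics along the binding CV (z-component of the displacement
// from the receptor anchor atom to the ligand nitrogen atom).
//
// Units: nm, ps, K, kJ/mol, atomic mass units (1 kJ/mol == 1 u nm^2 ps^-2).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ mol^-1 K^-1

// numerically safe logistic
static inline double sigmoid(double x) {
  if (x > 40.0) return 1.0;
  if (x < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// ---- potential terms -------------------------------------------------------

// One flat struct per supported term type; parsed once per call.
struct GaussWell { int atom; double cx, cy, cz, depth, width2; };
struct Harm      { int atom; double cx, cy, cz, k; };
struct HarmXY    { int atom; double k; };
struct QuarticZ  { int atom; double c4, c3, c2, c1, c0; };
struct Bond      { int i, j; double r0, k; };
struct Rep       { int i, j; double rcut, k; };
// receptor-body confinement: penalises transverse distance r > r0 when
// z is below the pocket mouth (sigmoidal gate of steepness mz at z0)
struct PocketWall { int atom; double r0, k, z0, mz; };

struct Terms {
  std::vector<GaussWell> gwell;
  std::vector<Harm>      harm;
  std::vector<HarmXY>    harmxy;
  std::vector<QuarticZ>  quart;
  std::vector<Bond>      bond;
  std::vector<Rep>       rep;
  std::vector<PocketWall> pwall;
};

static Terms parse_terms(const List& terms) {
  Terms T;
  for (int t = 0; t < terms.size(); ++t) {
    List trm = terms[t];
    std::string type = as<std::string>(trm["type"]);
    if (type == "gwell") {
      NumericVector c = trm["center"];
      double w = as<double>(trm["width"]);
      T.gwell.push_back({as<int>(trm["atom"]) - 1, c[0], c[1], c[2],
                         as<double>(trm["depth"]), w * w});
    } else if (type == "harm") {
      NumericVector c = trm["center"];
      T.harm.push_back({as<int>(trm["atom"]) - 1, c[0], c[1], c[2],
                        as<double>(trm["k"])});
    } else if (type == "harm_xy") {
      T.harmxy.push_back({as<int>(trm["atom"]) - 1, as<double>(trm["k"])});
    } else if (type == "quartic_z") {
      T.quart.push_back({as<int>(trm["atom"]) - 1, as<double>(trm["c4"]),
                         as<double>(trm["c3"]), as<double>(trm["c2"]),
                         as<double>(trm["c1"]), as<double>(trm["c0"])});
    } else if (type == "bond") {
      T.bond.push_back({as<int>(trm["i"]) - 1, as<int>(trm["j"]) - 1,
                        as<double>(trm["r0"]), as<double>(trm["k"])});
    } else if (type == "rep") {
      T.rep.push_back({as<int>(trm["i"]) - 1, as<int>(trm["j"]) - 1,
                       as<double>(trm["rcut"]), as<double>(trm["k"])});
    } else if (type == "pocket_wall") {
      T.pwall.push_back({as<int>(trm["atom"]) - 1, as<double>(trm["r0"]),
                         as<double>(trm["k"]), as<double>(trm["z0"]),
                         as<double>(trm["mz"])});
    } else {
      stop("unknown potential term type: " + type);
    }
  }
  return T;
}

// system potential energy and forces (adds into fx/fy/fz)
static double system_forces(const Terms& T,
                            const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& z,
                            std::vector<double>& fx,
                            std::vector<double>& fy,
                            std::vector<double>& fz) {
  double U = 0.0;
  for (const auto& g : T.gwell) {
    double dx = x[g.atom] - g.cx, dy = y[g.atom] - g.cy, dz = z[g.atom] - g.cz;
    double r2 = dx * dx + dy * dy + dz * dz;
    double e = std::exp(-r2 / (2.0 * g.width2));
    U -= g.depth * e;
    // U = -D e^{-r2/2w2};  dU/dx = D e (x-c)/w2 ;  force = -dU/dx
    double pref = -g.depth * e / g.width2;
    fx[g.atom] += pref * dx;
    fy[g.atom] += pref * dy;
    fz[g.atom] += pref * dz;
  }
  for (const auto& h : T.harm) {
    double dx = x[h.atom] - h.cx, dy = y[h.atom] - h.cy, dz = z[h.atom] - h.cz;
    U += 0.5 * h.k * (dx * dx + dy * dy + dz * dz);
    fx[h.atom] -= h.k * dx;
    fy[h.atom] -= h.k * dy;
    fz[h.atom] -= h.k * dz;
  }
  for (const auto& h : T.harmxy) {
    U += 0.5 * h.k * (x[h.atom] * x[h.atom] + y[h.atom] * y[h.atom]);
    fx[h.atom] -= h.k * x[h.atom];
    fy[h.atom] -= h.k * y[h.atom];
  }
  for (const auto& q : T.quart) {
    double s = z[q.atom];
    U += ((q.c4 * s + q.c3) * s + q.c2) * s * s + q.c1 * s + q.c0;
    double dU = ((4.0 * q.c4 * s + 3.0 * q.c3) * s + 2.0 * q.c2) * s + q.c1;
    fz[q.atom] -= dU;
  }
  for (const auto& b : T.bond) {
    double dx = x[b.i] - x[b.j], dy = y[b.i] - y[b.j], dz = z[b.i] - z[b.j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - b.r0;
    U += 0.5 * b.k * dr * dr;
    if (r > 1e-12) {
      double f = -b.k * dr / r;
      fx[b.i] += f * dx; fy[b.i] += f * dy; fz[b.i] += f * dz;
      fx[b.j] -= f * dx; fy[b.j] -= f * dy; fz[b.j] -= f * dz;
    }
  }
  for (const auto& p : T.rep) {
    double dx = x[p.i] - x[p.j], dy = y[p.i] - y[p.j], dz = z[p.i] - z[p.j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < p.rcut * p.rcut) {
      double r = std::sqrt(r2);
      double dr = p.rcut - r;
      U += 0.5 * p.k * dr * dr;
      if (r > 1e-12) {
        double f = p.k * dr / r; // repulsive, pushes apart
        fx[p.i] += f * dx; fy[p.i] += f * dy; fz[p.i] += f * dz;
        fx[p.j] -= f * dx; fy[p.j] -= f * dy; fz[p.j] -= f * dz;
      }
    }
  }
  for (const auto& p : T.pwall) {
    double r = std::sqrt(x[p.atom] * x[p.atom] + y[p.atom] * y[p.atom]);
    double ramp = r - p.r0;
    if (ramp > 0) {
      double gate = sigmoid(-p.mz * (z[p.atom] - p.z0));
      U += 0.5 * p.k * gate * ramp * ramp;
      if (r > 1e-12) {
        double fr = -p.k * gate * ramp / r;
        fx[p.atom] += fr * x[p.atom];
        fy[p.atom] += fr * y[p.atom];
      }
      // dU/dz = 0.5 k ramp^2 * dgate/dz,  dgate/dz = -mz * gate * (1 - gate)
      fz[p.atom] += 0.5 * p.k * ramp * ramp * p.mz * gate * (1.0 - gate);
    }
  }
  return U;
}

// ---- restraints ------------------------------------------------------------

struct Walls { bool on = false; double zlo = 0, zhi = 0, kappa = 0; };
struct Funnel { bool on = false; double d = 0, r1 = 0, m = 0, w = 0, h = 0, lam = 0; };

// harmonic CV walls, kappa*(z-z0)^2 outside the interval (no 1/2 factor)
static double wall_energy(double s, const Walls& W, double* dUds) {
  *dUds = 0.0;
  if (!W.on) return 0.0;
  if (s <= W.zlo) {
    double d = s - W.zlo;
    *dUds = 2.0 * W.kappa * d;
    return W.kappa * d * d;
  }
  if (s >= W.zhi) {
    double d = s - W.zhi;
    *dUds = 2.0 * W.kappa * d;
    return W.kappa * d * d;
  }
  return 0.0;
}

static double funnel_R(double z, const Funnel& F, double* dRdz) {
  double a = F.m * (z - F.w);
  if (a > 40.0) { *dRdz = 0.0; return F.r1; }
  if (a < -40.0) { *dRdz = 0.0; return F.d + F.r1; }
  double E = std::exp(a);
  double den = 1.0 + E;
  *dRdz = -F.d * F.m * E / (den * den);
  return F.d / den + F.r1;
}

// funnel restraint on the (x,y,z) displacement anchor -> ligand CV atom;
// returns energy, fills gradient wrt the displacement components
static double funnel_energy(double dx, double dy, double dz, const Funnel& F,
                            double* gx, double* gy, double* gz) {
  *gx = *gy = *gz = 0.0;
  if (!F.on) return 0.0;
  double r = std::sqrt(dx * dx + dy * dy);
  double dRdz;
  double R = funnel_R(dz, F, &dRdz);
  double g = r - R;
  double s = sigmoid(-F.lam * g); // = 1/(1+exp(lam*g))
  double U = F.h * (1.0 - s);
  double dUdg = F.h * F.lam * s * (1.0 - s);
  if (r > 1e-10) {
    *gx = dUdg * dx / r;
    *gy = dUdg * dy / r;
  }
  *gz = dUdg * (-dRdz);
  return U;
}

// ---- metadynamics bias grid ------------------------------------------------

struct MetaD {
  bool on = false;
  double w0 = 0, gamma = 0, sigma = 0;
  int stride = 0;
  double gmin = 0, gstep = 0;
  long long step_offset = 0;
  int walker_id = 0;
  double temperature = 0;
  NumericVector v; // bias V(s) on grid (shared, modified in place)
  NumericVector f; // dV/ds on grid
};

static inline double grid_interp(const NumericVector& g, double gmin,
                                 double gstep, int n, double s) {
  double u = (s - gmin) / gstep;
  if (u <= 0) return g[0];
  if (u >= n - 1) return g[n - 1];
  int i = (int)u;
  double frac = u - i;
  return g[i] * (1.0 - frac) + g[i + 1] * frac;
}

// ---- main integrator -------------------------------------------------------

// [[Rcpp::export]]
List ld_run_cpp(NumericMatrix coords0, NumericMatrix vels0,
                NumericVector masses, LogicalVector frozen, List terms,
                int cv_rec, int cv_lig,
                Nullable<List> walls_, Nullable<List> funnel_,
                Nullable<List> metad_,
                double dt, double friction, double temperature,
                int n_steps, int output_stride, double t0, int seed) {
  const int na = coords0.nrow();
  if (vels0.nrow() != na) stop("velocity array shape mismatch");
  Terms T = parse_terms(terms);

  Walls W;
  if (walls_.isNotNull()) {
    List wl(walls_);
    W.on = true;
    W.zlo = as<double>(wl["z_low"]);
    W.zhi = as<double>(wl["z_up"]);
    W.kappa = as<double>(wl["kappa"]);
  }
  Funnel F;
  if (funnel_.isNotNull()) {
    List fl(funnel_);
    F.on = true;
    F.d = as<double>(fl["d"]); F.r1 = as<double>(fl["r1"]);
    F.m = as<double>(fl["m"]); F.w = as<double>(fl["w"]);
    F.h = as<double>(fl["h"]); F.lam = as<double>(fl["lam"]);
  }
  MetaD M;
  if (metad_.isNotNull()) {
    List ml(metad_);
    M.on = true;
    M.w0 = as<double>(ml["w0"]);
    M.gamma = as<double>(ml["gamma"]);
    M.sigma = as<double>(ml["sigma"]);
    M.stride = as<int>(ml["stride"]);
    M.gmin = as<double>(ml["grid_min"]);
    M.gstep = as<double>(ml["grid_step"]);
    M.step_offset = (long long)as<double>(ml["step_offset"]);
    M.walker_id = as<int>(ml["walker_id"]);
    M.v = clone(as<NumericVector>(ml["bias_v"]));
    M.f = clone(as<NumericVector>(ml["bias_f"]));
    M.temperature = temperature;
  }
  const int ng = M.on ? M.v.size() : 0;
  const double dT = M.on ? (M.gamma - 1.0) * temperature : 0.0;

  std::vector<double> x(na), y(na), z(na), vx(na), vy(na), vz(na);
  for (int i = 0; i < na; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
    vx[i] = vels0(i, 0); vy[i] = vels0(i, 1); vz[i] = vels0(i, 2);
  }
  std::vector<double> fx(na), fy(na), fz(na);

  // BAOAB friction coefficients
  const double c1 = std::exp(-friction * dt);
  const double c2 = (friction > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> sdv(na); // per-atom thermal velocity scale
  for (int i = 0; i < na; ++i)
    sdv[i] = std::sqrt(KB * temperature / masses[i]);

  std::mt19937_64 rng((unsigned long long)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  std::normal_distribution<double> N01(0.0, 1.0);

  const int ri = cv_rec - 1, li = cv_lig - 1;

  // output buffers
  int nf = (output_stride > 0) ? n_steps / output_stride : 0;
  NumericVector traj(nf * na * 3);
  NumericVector f_time(nf), f_cv(nf), f_bias(nf), f_energy(nf);
  std::vector<double> hill_rows; // time, center, sigma, height, walker

  // force evaluation (system + restraints + metadynamics bias)
  auto eval_forces = [&](double* U_sys, double* U_restr, double* V_bias) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double U = system_forces(T, x, y, z, fx, fy, fz);
    double s = z[li] - z[ri];
    double dUds, gx, gy, gz;
    double Uw = wall_energy(s, W, &dUds);
    double Uf = funnel_energy(x[li] - x[ri], y[li] - y[ri], z[li] - z[ri],
                              F, &gx, &gy, &gz);
    fz[li] -= dUds; fz[ri] += dUds;
    fx[li] -= gx; fx[ri] += gx;
    fy[li] -= gy; fy[ri] += gy;
    fz[li] -= gz; fz[ri] += gz;
    double Vb = 0.0;
    if (M.on) {
      Vb = grid_interp(M.v, M.gmin, M.gstep, ng, s);
      double dVds = grid_interp(M.f, M.gmin, M.gstep, ng, s);
      fz[li] -= dVds; fz[ri] += dVds;
    }
    *U_sys = U; *U_restr = Uw + Uf; *V_bias = Vb;
  };

  double U_sys, U_restr, V_bias;
  eval_forces(&U_sys, &U_restr, &V_bias);

  int iframe = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < na; ++i) {
      if (frozen[i]) continue;
      double hdtm = 0.5 * dt / masses[i];
      vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
    }
    // A: half drift
    for (int i = 0; i < na; ++i) {
      if (frozen[i]) continue;
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    // O: thermostat
    if (friction > 0) {
      for (int i = 0; i < na; ++i) {
        if (frozen[i]) continue;
        vx[i] = c1 * vx[i] + c2 * sdv[i] * N01(rng);
        vy[i] = c1 * vy[i] + c2 * sdv[i] * N01(rng);
        vz[i] = c1 * vz[i] + c2 * sdv[i] * N01(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < na; ++i) {
      if (frozen[i]) continue;
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    // B: half kick with new forces
    eval_forces(&U_sys, &U_restr, &V_bias);
    for (int i = 0; i < na; ++i) {
      if (frozen[i]) continue;
      double hdtm = 0.5 * dt / masses[i];
      vx[i] += hdtm * fx[i]; vy[i] += hdtm * fy[i]; vz[i] += hdtm * fz[i];
    }

    if (!std::isfinite(U_sys) || !std::isfinite(x[li]))
      stop("integration failure (non-finite energy/coordinates) at step " +
           std::to_string(step));

    // well-tempered hill deposition
    if (M.on && ((M.step_offset + step) % M.stride == 0)) {
      double s = z[li] - z[ri];
      double vhere = grid_interp(M.v, M.gmin, M.gstep, ng, s);
      double height = M.w0 * std::exp(-vhere / (KB * dT));
      double inv2s2 = 1.0 / (2.0 * M.sigma * M.sigma);
      for (int gi = 0; gi < ng; ++gi) {
        double ds = (M.gmin + gi * M.gstep) - s;
        double e = height * std::exp(-ds * ds * inv2s2);
        M.v[gi] += e;
        // dV/ds at grid point sg for a hill centered at s: -(sg - s)/sigma^2 * e
        M.f[gi] += -ds / (M.sigma * M.sigma) * e;
      }
      hill_rows.push_back(t0 + step * dt);
      hill_rows.push_back(s);
      hill_rows.push_back(M.sigma);
      hill_rows.push_back(height);
      hill_rows.push_back((double)M.walker_id);
    }

    if (output_stride > 0 && step % output_stride == 0) {
      for (int i = 0; i < na; ++i) {
        traj[(size_t)iframe * na * 3 + i * 3 + 0] = x[i];
        traj[(size_t)iframe * na * 3 + i * 3 + 1] = y[i];
        traj[(size_t)iframe * na * 3 + i * 3 + 2] = z[i];
      }
      f_time[iframe] = t0 + step * dt;
      f_cv[iframe] = z[li] - z[ri];
      f_bias[iframe] = V_bias;
      f_energy[iframe] = U_sys + U_restr;
      ++iframe;
    }
  }

  NumericMatrix coords_out(na, 3), vels_out(na, 3);
  for (int i = 0; i < na; ++i) {
    coords_out(i, 0) = x[i]; coords_out(i, 1) = y[i]; coords_out(i, 2) = z[i];
    vels_out(i, 0) = vx[i]; vels_out(i, 1) = vy[i]; vels_out(i, 2) = vz[i];
  }
  int nh = hill_rows.size() / 5;
  NumericMatrix hills(nh, 5);
  for (int k = 0; k < nh; ++k)
    for (int c = 0; c < 5; ++c) hills(k, c) = hill_rows[k * 5 + c];

  return List::create(
      _["coords"] = coords_out, _["vels"] = vels_out,
      _["traj"] = traj, _["n_frames"] = iframe,
      _["time"] = f_time, _["cv"] = f_cv, _["bias"] = f_bias,
      _["energy"] = f_energy, _["hills"] = hills,
      _["final_time"] = t0 + n_steps * dt,
      _["bias_v"] = M.on ? M.v : NumericVector(0),
      _["bias_f"] = M.on ? M.f : NumericVector(0));
}

// system potential energy of a single configuration (no restraints)
// [[Rcpp::export]]
double potential_energy_cpp(NumericMatrix coords, List terms) {
  const int na = coords.nrow();
  Terms T = parse_terms(terms);
  std::vector<double> x(na), y(na), z(na), fx(na), fy(na), fz(na);
  for (int i = 0; i < na; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  return system_forces(T, x, y, z, fx, fy, fz);
}
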