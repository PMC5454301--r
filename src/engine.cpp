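// Coarse-grained MD engine: truncated LJ + cutoff Coulomb + harmonic
// bonds/angles in an orthorhombic periodic box, velocity-Verlet with
// optional Nose-Hoover thermostat, Berendsen barostat and imposed-flux
// (fixed-dE velocity-rescaling) NEMD exchange.
//
// Internal units: A, fs, amu, kcal/mol, K, e.  All randomness lives on the
// R side; every routine here is deterministic in its inputs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double MVSQ2E = 2390.0573615334906; // amu*(A/fs)^2 -> kcal/mol
static const double KB     = 0.0019872041;       // kcal/mol/K
static const double P2ATM  = 68568.415;          // kcal/mol/A^3 -> atm
static const double MIN_R2 = 1e-12;              // (1e-6 A)^2 overlap guard

struct Engine {
  int n;
  std::vector<double> x, v, f;   // 3n, interleaved xyz
  std::vector<double> m, q;
  std::vector<int> type;         // 0-based
  int ntypes;
  std::vector<double> eps, sg2, ush; // ntypes^2 tables (sg2 = sigma^2)
  double rc, rc2, kcoul;
  int coul_mode;                 // 0 plain truncated, 1 force-shifted
  double L[3];
  // bonded terms (0-based indices)
  std::vector<int> b1, b2; std::vector<double> bk, br0;
  std::vector<int> a1, a2, a3; std::vector<double> ak, ath0;
  std::vector<std::vector<int>> excl; // sorted nonbonded exclusions
  // neighbour list (with per-pair periodic shifts, fixed between rebuilds)
  double skin;
  std::vector<int> nli, nlj;
  std::vector<double> nls; // 3 shifts per pair
  std::vector<double> xbuild;
  // last-computed energies / virial
  double evdw, ecoul, ebond, eangle;
  double W[3];

  double wrap(double d, int ax) const { return d - L[ax] * std::round(d / L[ax]); }

  bool excluded(int i, int j) const {
    const std::vector<int> &e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }

  void add_excl(int i, int j) { excl[i].push_back(j); excl[j].push_back(i); }

  void finish_excl() {
    for (auto &e : excl) { std::sort(e.begin(), e.end()); e.erase(std::unique(e.begin(), e.end()), e.end()); }
  }

  void try_pair(int i, int j, double rl2) {
    double sx = -L[0] * std::round((x[3*i]   - x[3*j])   / L[0]);
    double sy = -L[1] * std::round((x[3*i+1] - x[3*j+1]) / L[1]);
    double sz = -L[2] * std::round((x[3*i+2] - x[3*j+2]) / L[2]);
    double dx = x[3*i] - x[3*j] + sx;
    double dy = x[3*i+1] - x[3*j+1] + sy;
    double dz = x[3*i+2] - x[3*j+2] + sz;
    if (dx*dx + dy*dy + dz*dz < rl2 && !excluded(i, j)) {
      nli.push_back(i); nlj.push_back(j);
      nls.push_back(sx); nls.push_back(sy); nls.push_back(sz);
    }
  }

  void build_neighbors() {
    nli.clear(); nlj.clear(); nls.clear();
    double rl = rc + skin, rl2 = rl * rl;
    int nc[3];
    for (int a = 0; a < 3; ++a) nc[a] = std::max(1, (int)(L[a] / rl));
    long ncells = (long)nc[0] * nc[1] * nc[2];
    if (n < 200 || ncells < 27) {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) try_pair(i, j, rl2);
    } else {
      std::vector<std::vector<int>> cells(ncells);
      std::vector<int> ci(n);
      for (int i = 0; i < n; ++i) {
        int c[3];
        for (int a = 0; a < 3; ++a) {
          double w = x[3*i+a];
          w -= L[a] * std::floor(w / L[a]);
          c[a] = std::min((int)(w / L[a] * nc[a]), nc[a] - 1);
        }
        ci[i] = (c[0] * nc[1] + c[1]) * nc[2] + c[2];
        cells[ci[i]].push_back(i);
      }
      for (int cx = 0; cx < nc[0]; ++cx)
        for (int cy = 0; cy < nc[1]; ++cy)
          for (int cz = 0; cz < nc[2]; ++cz) {
            int c0 = (cx * nc[1] + cy) * nc[2] + cz;
            for (int ox = -1; ox <= 1; ++ox)
              for (int oy = -1; oy <= 1; ++oy)
                for (int oz = -1; oz <= 1; ++oz) {
                  int c1 = (((cx + ox + nc[0]) % nc[0]) * nc[1] +
                            (cy + oy + nc[1]) % nc[1]) * nc[2] +
                           (cz + oz + nc[2]) % nc[2];
                  if (c1 < c0) continue;
                  for (int i : cells[c0])
                    for (int j : cells[c1]) {
                      if (c1 == c0 && j <= i) continue;
                      try_pair(std::min(i, j), std::max(i, j), rl2);
                    }
                }
          }
      // de-duplicate: neighbouring cell pairs can repeat when nc[a] <= 2
      if (nc[0] <= 2 || nc[1] <= 2 || nc[2] <= 2) dedup_pairs();
    }
    xbuild = x;
  }

  void dedup_pairs() {
    std::vector<long> key(nli.size());
    std::vector<size_t> ord(nli.size());
    for (size_t p = 0; p < nli.size(); ++p) {
      key[p] = (long)nli[p] * n + nlj[p];
      ord[p] = p;
    }
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return key[a] < key[b]; });
    std::vector<int> i2, j2; std::vector<double> s2;
    long prev = -1;
    for (size_t p : ord) {
      if (key[p] == prev) continue;
      prev = key[p];
      i2.push_back(nli[p]); j2.push_back(nlj[p]);
      s2.push_back(nls[3*p]); s2.push_back(nls[3*p+1]); s2.push_back(nls[3*p+2]);
    }
    nli.swap(i2); nlj.swap(j2); nls.swap(s2);
  }

  bool need_rebuild() const {
    double half = 0.5 * skin, h2 = half * half, mx = 0.0;
    for (int i = 0; i < 3 * n; ++i) {
      double d = x[i] - xbuild[i];
      double d2 = d * d;
      if (d2 > mx) mx = d2;
    }
    return mx > h2;
  }

  void compute_forces() {
    std::fill(f.begin(), f.end(), 0.0);
    evdw = ecoul = ebond = eangle = 0.0;
    W[0] = W[1] = W[2] = 0.0;
    const size_t np = nli.size();
    for (size_t p = 0; p < np; ++p) {
      int i = nli[p], j = nlj[p];
      double dx = x[3*i]   - x[3*j]   + nls[3*p];
      double dy = x[3*i+1] - x[3*j+1] + nls[3*p+1];
      double dz = x[3*i+2] - x[3*j+2] + nls[3*p+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      if (r2 < MIN_R2)
        stop("degenerate configuration: particles %d and %d closer than 1e-6 A", i + 1, j + 1);
      int tp = type[i] * ntypes + type[j];
      double fpr = 0.0; // (dE/dr)/r with sign so that f_i += fpr*dr
      double e = eps[tp];
      if (e > 0.0) {
        double sr2 = sg2[tp] / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        evdw += 4.0 * e * (sr12 - sr6) - ush[tp];
        fpr += 24.0 * e * (2.0 * sr12 - sr6) / r2;
      }
      double qq = q[i] * q[j];
      if (kcoul != 0.0 && qq != 0.0) {
        double r = std::sqrt(r2);
        if (coul_mode == 1) {
          ecoul += kcoul * qq * (1.0 / r - 1.0 / rc + (r - rc) / (rc * rc));
          fpr += kcoul * qq * (1.0 / r2 - 1.0 / (rc * rc)) / r;
        } else {
          ecoul += kcoul * qq / r;
          fpr += kcoul * qq / (r2 * r);
        }
      }
      if (fpr != 0.0) {
        double fx = fpr * dx, fy = fpr * dy, fz = fpr * dz;
        f[3*i] += fx; f[3*i+1] += fy; f[3*i+2] += fz;
        f[3*j] -= fx; f[3*j+1] -= fy; f[3*j+2] -= fz;
        W[0] += fx * dx; W[1] += fy * dy; W[2] += fz * dz;
      }
    }
    // bonds: E = 1/2 k (r - r0)^2
    for (size_t b = 0; b < b1.size(); ++b) {
      int i = b1[b], j = b2[b];
      double dx = wrap(x[3*i]   - x[3*j],   0);
      double dy = wrap(x[3*i+1] - x[3*j+1], 1);
      double dz = wrap(x[3*i+2] - x[3*j+2], 2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-6) stop("degenerate bond %d: zero length", (int)b + 1);
      double dr = r - br0[b];
      ebond += 0.5 * bk[b] * dr * dr;
      double fpr = -bk[b] * dr / r;
      double fx = fpr * dx, fy = fpr * dy, fz = fpr * dz;
      f[3*i] += fx; f[3*i+1] += fy; f[3*i+2] += fz;
      f[3*j] -= fx; f[3*j+1] -= fy; f[3*j+2] -= fz;
      W[0] += fx * dx; W[1] += fy * dy; W[2] += fz * dz;
    }
    // angles: E = 1/2 k (theta - theta0)^2 on (i, j, k), j central
    for (size_t t = 0; t < a1.size(); ++t) {
      int i = a1[t], j = a2[t], k = a3[t];
      double ax = wrap(x[3*i]   - x[3*j],   0);
      double ay = wrap(x[3*i+1] - x[3*j+1], 1);
      double az = wrap(x[3*i+2] - x[3*j+2], 2);
      double bx = wrap(x[3*k]   - x[3*j],   0);
      double by = wrap(x[3*k+1] - x[3*j+1], 1);
      double bz = wrap(x[3*k+2] - x[3*j+2], 2);
      double la2 = ax*ax + ay*ay + az*az, lb2 = bx*bx + by*by + bz*bz;
      double la = std::sqrt(la2), lb = std::sqrt(lb2);
      double c = (ax*bx + ay*by + az*bz) / (la * lb);
      c = std::max(-1.0, std::min(1.0, c));
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double th = std::acos(c);
      double dth = th - ath0[t];
      eangle += 0.5 * ak[t] * dth * dth;
      double aa = -ak[t] * dth / s;
      double a11 = aa * c / la2, a12 = -aa / (la * lb), a22 = aa * c / lb2;
      double f1x = a11*ax + a12*bx, f1y = a11*ay + a12*by, f1z = a11*az + a12*bz;
      double f3x = a22*bx + a12*ax, f3y = a22*by + a12*ay, f3z = a22*bz + a12*az;
      f[3*i] += f1x; f[3*i+1] += f1y; f[3*i+2] += f1z;
      f[3*k] += f3x; f[3*k+1] += f3y; f[3*k+2] += f3z;
      f[3*j] -= f1x + f3x; f[3*j+1] -= f1y + f3y; f[3*j+2] -= f1z + f3z;
      W[0] += f1x * ax + f3x * bx;
      W[1] += f1y * ay + f3y * by;
      W[2] += f1z * az + f3z * bz;
    }
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += m[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    return 0.5 * ke * MVSQ2E;
  }

  double epot() const { return evdw + ecoul + ebond + eangle; }
};

static void fill_engine(Engine &E, NumericMatrix pos, NumericMatrix vel,
                        NumericVector mass, NumericVector charge,
                        IntegerVector type, List ff, NumericVector boxlen) {
  E.n = pos.nrow();
  E.x.resize(3 * E.n); E.v.resize(3 * E.n); E.f.assign(3 * E.n, 0.0);
  E.m.resize(E.n); E.q.resize(E.n); E.type.resize(E.n);
  for (int i = 0; i < E.n; ++i) {
    for (int a = 0; a < 3; ++a) { E.x[3*i+a] = pos(i, a); E.v[3*i+a] = vel(i, a); }
    E.m[i] = mass[i]; E.q[i] = charge[i]; E.type[i] = type[i] - 1;
  }
  for (int a = 0; a < 3; ++a) E.L[a] = boxlen[a];
  NumericMatrix em = ff["eps"], sm = ff["sigma"];
  E.ntypes = em.nrow();
  int nt = E.ntypes;
  E.eps.resize(nt * nt); E.sg2.resize(nt * nt); E.ush.assign(nt * nt, 0.0);
  E.rc = as<double>(ff["cutoff"]); E.rc2 = E.rc * E.rc;
  bool ljsh = as<bool>(ff["lj_shift"]);
  for (int i = 0; i < nt; ++i) for (int j = 0; j < nt; ++j) {
    E.eps[i*nt+j] = em(i, j);
    E.sg2[i*nt+j] = sm(i, j) * sm(i, j);
    if (ljsh && em(i, j) > 0) {
      double sr6 = std::pow(sm(i, j) * sm(i, j) / E.rc2, 3.0);
      E.ush[i*nt+j] = 4.0 * em(i, j) * (sr6 * sr6 - sr6);
    }
  }
  E.kcoul = as<double>(ff["coulomb_k"]);
  E.coul_mode = as<int>(ff["coul_mode"]);
  E.skin = as<double>(ff["skin"]);
  E.excl.assign(E.n, {});
  E.b1.clear(); E.b2.clear(); E.bk.clear(); E.br0.clear();
  if (!Rf_isNull(ff["bonds"])) {
    NumericMatrix B = ff["bonds"];
    for (int b = 0; b < B.nrow(); ++b) {
      int i = (int)B(b, 0) - 1, j = (int)B(b, 1) - 1;
      E.b1.push_back(i); E.b2.push_back(j);
      E.bk.push_back(B(b, 2)); E.br0.push_back(B(b, 3));
      E.add_excl(i, j);
    }
  }
  E.a1.clear(); E.a2.clear(); E.a3.clear(); E.ak.clear(); E.ath0.clear();
  if (!Rf_isNull(ff["angles"])) {
    NumericMatrix A = ff["angles"];
    for (int t = 0; t < A.nrow(); ++t) {
      int i = (int)A(t, 0) - 1, j = (int)A(t, 1) - 1, k = (int)A(t, 2) - 1;
      E.a1.push_back(i); E.a2.push_back(j); E.a3.push_back(k);
      E.ak.push_back(A(t, 3)); E.ath0.push_back(A(t, 4));
    }
  }
  // 1-3 exclusions from the bond graph (any two particles sharing a bonded
  // neighbour), independent of whether an angle term is defined
  {
    std::vector<std::vector<int>> adj(E.n);
    for (size_t b = 0; b < E.b1.size(); ++b) {
      adj[E.b1[b]].push_back(E.b2[b]);
      adj[E.b2[b]].push_back(E.b1[b]);
    }
    for (int j = 0; j < E.n; ++j)
      for (size_t a = 0; a + 1 < adj[j].size(); ++a)
        for (size_t b = a + 1; b < adj[j].size(); ++b)
          E.add_excl(adj[j][a], adj[j][b]);
  }
  E.finish_excl();
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                NumericVector charge, IntegerVector type, List ff,
                NumericVector boxlen) {
  Engine E;
  fill_engine(E, pos, vel, mass, charge, type, ff, boxlen);
  E.build_neighbors();
  E.compute_forces();
  NumericMatrix fo(E.n, 3);
  for (int i = 0; i < E.n; ++i) for (int a = 0; a < 3; ++a) fo(i, a) = E.f[3*i+a];
  return List::create(_["forces"] = fo,
                      _["evdw"] = E.evdw, _["ecoul"] = E.ecoul,
                      _["ebond"] = E.ebond, _["eangle"] = E.eangle,
                      _["kinetic"] = E.kinetic(),
                      _["virial"] = NumericVector::create(E.W[0], E.W[1], E.W[2]));
}

// Cross-group nonbonded energy (LJ + Coulomb) between two disjoint index
// sets, same cutoff/exclusion rules as the engine.  Brute-force A x B loop.
// [[Rcpp::export]]
List cpp_cross_energy(NumericMatrix pos, NumericVector charge, IntegerVector type,
                      List ff, NumericVector boxlen,
                      IntegerVector selA, IntegerVector selB) {
  Engine E;
  NumericMatrix vel(pos.nrow(), 3);
  NumericVector mass(pos.nrow(), 1.0);
  fill_engine(E, pos, vel, mass, charge, type, ff, boxlen);
  double evdw = 0.0, ecoul = 0.0;
  for (int a = 0; a < selA.size(); ++a) {
    int i = selA[a] - 1;
    for (int b = 0; b < selB.size(); ++b) {
      int j = selB[b] - 1;
      if (i == j) stop("selections overlap at particle %d", i + 1);
      if (E.excluded(i, j)) continue;
      double dx = E.wrap(E.x[3*i]   - E.x[3*j],   0);
      double dy = E.wrap(E.x[3*i+1] - E.x[3*j+1], 1);
      double dz = E.wrap(E.x[3*i+2] - E.x[3*j+2], 2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= E.rc2) continue;
      int tp = E.type[i] * E.ntypes + E.type[j];
      double e = E.eps[tp];
      if (e > 0.0) {
        double sr6 = std::pow(E.sg2[tp] / r2, 3.0);
        evdw += 4.0 * e * (sr6 * sr6 - sr6) - E.ush[tp];
      }
      double qq = E.q[i] * E.q[j];
      if (E.kcoul != 0.0 && qq != 0.0) {
        double r = std::sqrt(r2);
        if (E.coul_mode == 1)
          ecoul += E.kcoul * qq * (1.0 / r - 1.0 / E.rc + (r - E.rc) / (E.rc * E.rc));
        else
          ecoul += E.kcoul * qq / r;
      }
    }
  }
  return List::create(_["evdw"] = evdw, _["ecoul"] = ecoul);
}

// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix pos, NumericVector boxlen) {
  int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i) for (int j = i + 1; j < n; ++j) {
    double d2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = pos(i, a) - pos(j, a);
      d -= boxlen[a] * std::round(d / boxlen[a]);
      d2 += d * d;
    }
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

// Adaptive steepest descent; returns relaxed positions and final max |f|.
// [[Rcpp::export]]
List cpp_steepest_descent(NumericMatrix pos, NumericVector mass, NumericVector charge,
                          IntegerVector type, List ff, NumericVector boxlen,
                          int n_steps, double max_disp) {
  Engine E;
  NumericMatrix vel(pos.nrow(), 3);
  fill_engine(E, pos, vel, mass, charge, type, ff, boxlen);
  E.build_neighbors();
  E.compute_forces();
  double e0 = E.epot(), gamma = 1e-3;
  std::vector<double> xprev;
  for (int s = 0; s < n_steps; ++s) {
    xprev = E.x;
    double fmax = 0.0;
    for (int i = 0; i < 3 * E.n; ++i) fmax = std::max(fmax, std::fabs(E.f[i]));
    if (fmax < 1e-10) break;
    double scale = std::min(gamma, max_disp / fmax);
    for (int i = 0; i < 3 * E.n; ++i) E.x[i] += scale * E.f[i];
    if (E.need_rebuild()) E.build_neighbors();
    E.compute_forces();
    double e1 = E.epot();
    if (e1 < e0) { e0 = e1; gamma *= 1.1; }
    else { E.x = xprev; E.build_neighbors(); E.compute_forces(); gamma *= 0.5; }
  }
  double fmax = 0.0;
  for (int i = 0; i < 3 * E.n; ++i) fmax = std::max(fmax, std::fabs(E.f[i]));
  NumericMatrix out(E.n, 3);
  for (int i = 0; i < E.n; ++i) for (int a = 0; a < 3; ++a) out(i, a) = E.x[3*i+a];
  return List::create(_["positions"] = out, _["fmax"] = fmax, _["epot"] = e0);
}

// Main MD driver.  ctrl is a list; see run_md() on the R side for the keys.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                NumericVector charge, IntegerVector type, List ff,
                NumericVector boxlen, List ctrl) {
  Engine E;
  fill_engine(E, pos, vel, mass, charge, type, ff, boxlen);

  const int n_steps     = as<int>(ctrl["n_steps"]);
  const double dt       = as<double>(ctrl["dt"]);
  const int thermo      = as<int>(ctrl["thermo"]);      // 0 none, 1 Nose-Hoover
  const double T0       = as<double>(ctrl["T0"]);
  const double T1       = as<double>(ctrl["T1"]);
  const double tauT     = as<double>(ctrl["tau_T"]);
  const int baro        = as<int>(ctrl["baro"]);        // 0 none, 1 Berendsen
  const double Ptarget  = as<double>(ctrl["target_P"]); // atm
  const double tauP     = as<double>(ctrl["tau_P"]);
  const double betaP    = as<double>(ctrl["beta_P"]);   // atm^-1
  const int p_axis      = as<int>(ctrl["p_axis"]);      // 0 iso, 1 z-only
  const double dof      = as<double>(ctrl["dof"]);
  const int log_every   = as<int>(ctrl["log_every"]);
  const int traj_every  = as<int>(ctrl["traj_every"]);
  const int sample_every= as<int>(ctrl["sample_every"]);
  const int n_layers    = as<int>(ctrl["n_layers"]);
  const int hot         = as<int>(ctrl["hot"]);         // 0-based, -1 = off
  const int cold        = as<int>(ctrl["cold"]);
  const double dE       = as<double>(ctrl["delta_e"]);
  const int interval    = as<int>(ctrl["interval"]);
  const bool track_min  = as<bool>(ctrl["track_min"]);
  IntegerVector group   = ctrl["group"];   // 0 W, 1 H, 2 T (len n or 0)
  IntegerVector leaflet = ctrl["leaflet"]; // -1/0/1

  const bool nemd = hot >= 0 && cold >= 0 && interval > 0;
  const double dt2 = 0.5 * dt;

  E.build_neighbors();
  E.compute_forces();

  // logging storage
  int n_logs = log_every > 0 ? n_steps / log_every : 0;
  NumericMatrix logm(n_logs, 12);
  int li = 0;

  int n_frames = traj_every > 0 ? n_steps / traj_every : 0;
  List traj_pos(n_frames), traj_vel(n_frames);
  IntegerVector traj_step(n_frames);
  int fi = 0;

  int n_samp = sample_every > 0 ? n_steps / sample_every : 0;
  NumericMatrix layer_ke(n_samp, n_layers > 0 ? n_layers : 1);
  IntegerMatrix layer_cnt(n_samp, n_layers > 0 ? n_layers : 1);
  NumericMatrix comp(n_layers > 0 ? n_layers : 1, 3);
  NumericMatrix leaf(n_layers > 0 ? n_layers : 1, 2);
  int si = 0;

  int n_ex = nemd ? n_steps / interval : 0;
  NumericMatrix ledger(n_ex, 8); // step, applied, keC0, keC1, keH0, keH1, dpmax, cumE
  int ei = 0;
  double cumE = 0.0;

  double xi = 0.0; // Nose-Hoover friction
  double min_e = R_PosInf;
  std::vector<double> min_x, min_v;

  std::vector<int> layer_of(E.n);
  std::vector<int> hot_idx, cold_idx;

  auto assign_all = [&]() {
    double Lz = E.L[2];
    for (int i = 0; i < E.n; ++i) {
      double z = E.x[3*i+2];
      z -= Lz * std::floor(z / Lz);
      int l = (int)(n_layers * z / Lz);
      if (l >= n_layers) l = n_layers - 1;
      layer_of[i] = l;
    }
  };

  for (int step = 1; step <= n_steps; ++step) {
    double Ttarget = T0 + (T1 - T0) * ((double)step / n_steps);
    if (thermo == 1) {
      double K = E.kinetic();
      double Q = dof * KB * Ttarget * tauT * tauT;
      xi += dt2 * (2.0 * K - dof * KB * Ttarget) / Q;
      double sc = std::exp(std::max(-30.0, std::min(30.0, -xi * dt2)));
      for (int i = 0; i < 3 * E.n; ++i) E.v[i] *= sc;
    }
    // half kick + drift
    for (int i = 0; i < E.n; ++i) {
      double im = dt2 / (E.m[i] * MVSQ2E);
      for (int a = 0; a < 3; ++a) {
        E.v[3*i+a] += im * E.f[3*i+a];
        E.x[3*i+a] += dt * E.v[3*i+a];
      }
    }
    if (E.need_rebuild()) E.build_neighbors();
    E.compute_forces();
    for (int i = 0; i < E.n; ++i) {
      double im = dt2 / (E.m[i] * MVSQ2E);
      for (int a = 0; a < 3; ++a) E.v[3*i+a] += im * E.f[3*i+a];
    }
    if (thermo == 1) {
      double K = E.kinetic();
      double Q = dof * KB * Ttarget * tauT * tauT;
      xi += dt2 * (2.0 * K - dof * KB * Ttarget) / Q;
      double sc = std::exp(std::max(-30.0, std::min(30.0, -xi * dt2)));
      for (int i = 0; i < 3 * E.n; ++i) E.v[i] *= sc;
    }
    if (baro == 1) {
      double V = E.L[0] * E.L[1] * E.L[2];
      double kea[3] = {0, 0, 0};
      for (int i = 0; i < E.n; ++i)
        for (int a = 0; a < 3; ++a) kea[a] += E.m[i] * E.v[3*i+a] * E.v[3*i+a];
      double Paxis;
      if (p_axis == 1) {
        Paxis = (kea[2] * MVSQ2E + E.W[2]) / V * P2ATM;
        double mu = std::cbrt(1.0 - betaP * dt / tauP * (Ptarget - Paxis));
        mu = std::max(0.9, std::min(1.1, mu));
        E.L[2] *= mu;
        for (int i = 0; i < E.n; ++i) E.x[3*i+2] *= mu;
        for (size_t p = 2; p < E.nls.size(); p += 3) E.nls[p] *= mu;
      } else {
        double Psum = ((kea[0] + kea[1] + kea[2]) * MVSQ2E + E.W[0] + E.W[1] + E.W[2]) / (3.0 * V) * P2ATM;
        Paxis = Psum;
        double mu = std::cbrt(1.0 - betaP * dt / tauP * (Ptarget - Psum));
        mu = std::max(0.9, std::min(1.1, mu));
        for (int a = 0; a < 3; ++a) E.L[a] *= mu;
        for (int i = 0; i < 3 * E.n; ++i) E.x[i] *= mu;
        for (size_t p = 0; p < E.nls.size(); ++p) E.nls[p] *= mu;
      }
      if (E.need_rebuild()) E.build_neighbors();
    }

    if (nemd && step % interval == 0) {
      assign_all();
      hot_idx.clear(); cold_idx.clear();
      for (int i = 0; i < E.n; ++i) {
        if (layer_of[i] == hot) hot_idx.push_back(i);
        else if (layer_of[i] == cold) cold_idx.push_back(i);
      }
      double keC0 = NA_REAL, keC1 = NA_REAL, keH0 = NA_REAL, keH1 = NA_REAL;
      double dpmax = 0.0;
      bool applied = false;
      auto layer_ke_tot = [&](std::vector<int> &idx) {
        double k = 0.0;
        for (int i : idx)
          k += E.m[i] * (E.v[3*i]*E.v[3*i] + E.v[3*i+1]*E.v[3*i+1] + E.v[3*i+2]*E.v[3*i+2]);
        return 0.5 * k * MVSQ2E;
      };
      if ((int)hot_idx.size() >= 2 && (int)cold_idx.size() >= 2 && dE != 0.0) {
        // cold layer relative KE
        double Mc = 0.0, pc[3] = {0, 0, 0};
        for (int i : cold_idx) {
          Mc += E.m[i];
          for (int a = 0; a < 3; ++a) pc[a] += E.m[i] * E.v[3*i+a];
        }
        double vcomC[3] = {pc[0] / Mc, pc[1] / Mc, pc[2] / Mc};
        double KrelC = 0.0;
        for (int i : cold_idx)
          for (int a = 0; a < 3; ++a) {
            double dv = E.v[3*i+a] - vcomC[a];
            KrelC += E.m[i] * dv * dv;
          }
        KrelC *= 0.5 * MVSQ2E;
        if (KrelC > dE) {
          keC0 = layer_ke_tot(cold_idx); keH0 = layer_ke_tot(hot_idx);
          double p0[3] = {0, 0, 0}, p1[3] = {0, 0, 0};
          for (int i : cold_idx) for (int a = 0; a < 3; ++a) p0[a] += E.m[i] * E.v[3*i+a];
          double alC = std::sqrt(1.0 - dE / KrelC);
          for (int i : cold_idx)
            for (int a = 0; a < 3; ++a)
              E.v[3*i+a] = vcomC[a] + alC * (E.v[3*i+a] - vcomC[a]);
          for (int i : cold_idx) for (int a = 0; a < 3; ++a) p1[a] += E.m[i] * E.v[3*i+a];
          for (int a = 0; a < 3; ++a) dpmax = std::max(dpmax, std::fabs(p1[a] - p0[a]));
          // hot layer
          double Mh = 0.0, ph[3] = {0, 0, 0};
          for (int i : hot_idx) {
            Mh += E.m[i];
            for (int a = 0; a < 3; ++a) ph[a] += E.m[i] * E.v[3*i+a];
          }
          double vcomH[3] = {ph[0] / Mh, ph[1] / Mh, ph[2] / Mh};
          double KrelH = 0.0;
          for (int i : hot_idx)
            for (int a = 0; a < 3; ++a) {
              double dv = E.v[3*i+a] - vcomH[a];
              KrelH += E.m[i] * dv * dv;
            }
          KrelH *= 0.5 * MVSQ2E;
          double q0[3] = {0, 0, 0}, q1[3] = {0, 0, 0};
          for (int i : hot_idx) for (int a = 0; a < 3; ++a) q0[a] += E.m[i] * E.v[3*i+a];
          double alH = std::sqrt(1.0 + dE / KrelH);
          for (int i : hot_idx)
            for (int a = 0; a < 3; ++a)
              E.v[3*i+a] = vcomH[a] + alH * (E.v[3*i+a] - vcomH[a]);
          for (int i : hot_idx) for (int a = 0; a < 3; ++a) q1[a] += E.m[i] * E.v[3*i+a];
          for (int a = 0; a < 3; ++a) dpmax = std::max(dpmax, std::fabs(q1[a] - q0[a]));
          keC1 = layer_ke_tot(cold_idx); keH1 = layer_ke_tot(hot_idx);
          cumE += dE;
          applied = true;
        }
      } else if (dE == 0.0) {
        applied = true; // identity exchange, counted but bitwise no-op
      }
      if (ei < n_ex) {
        ledger(ei, 0) = step; ledger(ei, 1) = applied ? 1 : 0;
        ledger(ei, 2) = keC0; ledger(ei, 3) = keC1;
        ledger(ei, 4) = keH0; ledger(ei, 5) = keH1;
        ledger(ei, 6) = dpmax; ledger(ei, 7) = cumE;
        ++ei;
      }
    }

    if (sample_every > 0 && step % sample_every == 0 && si < n_samp) {
      assign_all();
      for (int i = 0; i < E.n; ++i) {
        int l = layer_of[i];
        double k = 0.5 * E.m[i] * (E.v[3*i]*E.v[3*i] + E.v[3*i+1]*E.v[3*i+1] + E.v[3*i+2]*E.v[3*i+2]) * MVSQ2E;
        layer_ke(si, l) += k;
        layer_cnt(si, l) += 1;
        if (group.size() == E.n) {
          comp(l, group[i]) += 1.0;
          if (group[i] == 2 && leaflet.size() == E.n && leaflet[i] >= 0)
            leaf(l, leaflet[i]) += 1.0;
        }
      }
      ++si;
    }

    if (log_every > 0 && step % log_every == 0 && li < n_logs) {
      double K = E.kinetic();
      double V = E.L[0] * E.L[1] * E.L[2];
      double kea = 2.0 * K; // sum m v^2 in kcal/mol
      double P = (kea + E.W[0] + E.W[1] + E.W[2]) / (3.0 * V) * P2ATM;
      double Pz = 0.0;
      {
        double kz = 0.0;
        for (int i = 0; i < E.n; ++i) kz += E.m[i] * E.v[3*i+2] * E.v[3*i+2];
        Pz = (kz * MVSQ2E + E.W[2]) / V * P2ATM;
      }
      double ep = E.epot(), et = ep + K;
      if (!std::isfinite(et))
        stop("instability: non-finite total energy at step %d", step);
      logm(li, 0) = step; logm(li, 1) = step * dt;
      logm(li, 2) = 2.0 * K / (dof * KB);
      logm(li, 3) = P; logm(li, 4) = Pz; logm(li, 5) = V;
      logm(li, 6) = E.evdw; logm(li, 7) = E.ecoul;
      logm(li, 8) = E.ebond; logm(li, 9) = E.eangle;
      logm(li, 10) = K; logm(li, 11) = et;
      if (track_min && ep < min_e) { min_e = ep; min_x = E.x; min_v = E.v; }
      ++li;
    }

    if (traj_every > 0 && step % traj_every == 0 && fi < n_frames) {
      NumericMatrix P(E.n, 3), Vv(E.n, 3);
      for (int i = 0; i < E.n; ++i) for (int a = 0; a < 3; ++a) {
        P(i, a) = E.x[3*i+a]; Vv(i, a) = E.v[3*i+a];
      }
      traj_pos[fi] = P; traj_vel[fi] = Vv; traj_step[fi] = step;
      ++fi;
    }
  }

  NumericMatrix Pf(E.n, 3), Vf(E.n, 3);
  for (int i = 0; i < E.n; ++i) for (int a = 0; a < 3; ++a) {
    Pf(i, a) = E.x[3*i+a]; Vf(i, a) = E.v[3*i+a];
  }
  List out = List::create(
    _["positions"] = Pf, _["velocities"] = Vf,
    _["box"] = NumericVector::create(E.L[0], E.L[1], E.L[2]),
    _["log"] = logm, _["traj_pos"] = traj_pos, _["traj_vel"] = traj_vel,
    _["traj_step"] = traj_step,
    _["layer_ke"] = layer_ke, _["layer_cnt"] = layer_cnt,
    _["composition"] = comp, _["leaflet_comp"] = leaf,
    _["n_layer_samples"] = si,
    _["ledger"] = ledger, _["cum_energy"] = cumE);
  if (track_min && min_x.size() == (size_t)(3 * E.n)) {
    NumericMatrix Mp(E.n, 3), Mv(E.n, 3);
    for (int i = 0; i < E.n; ++i) for (int a = 0; a < 3; ++a) {
      Mp(i, a) = min_x[3*i+a]; Mv(i, a) = min_v[3*i+a];
    }
    out["min_positions"] = Mp; out["min_velocities"] = Mv; out["min_epot"] = min_e;
  }
  return out;
}
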