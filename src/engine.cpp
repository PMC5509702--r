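// Minimal particle-dynamics core: truncated-shifted 12-6 pair potential with
// cell lists, harmonic breakable bonds, velocity-Verlet integration with
// periodic lateral boundaries and elastic reflective walls on the shock axis
// (the last coordinate), and a weak-coupling thermostat for equilibration.
//
// Units are reduced Lennard-Jones units throughout. Bond indices arrive
// 1-based from R and are converted here.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// 12-6 pair potential truncated at rcut with energy AND force shifted to
// zero at the cutoff (shifted-force form): U_sf(r) = U(r) - U(rc)
// - (r - rc) U'(rc). The force shift removes the discontinuity in the force
// at the cutoff, which would otherwise dominate NVE energy drift.
struct PairPot {
  double sigma, eps, rcut, rcut2, ushift, fcut;
  PairPot(double s, double e, double rc) : sigma(s), eps(e), rcut(rc) {
    rcut2 = rc * rc;
    double sr6 = std::pow(s / rc, 6.0);
    double sr12 = sr6 * sr6;
    fcut = 24.0 * e * (2.0 * sr12 - sr6) / rc;  // -U'(rc)
    ushift = 4.0 * e * (sr12 - sr6);
  }
  // returns shifted u(r); sets fr = -dU_sf/dr / r (force prefactor)
  inline double eval(double r2, double &fr) const {
    double r = std::sqrt(r2);
    double sr2 = sigma * sigma / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    fr = (24.0 * eps * (2.0 * sr12 - sr6) / r - fcut) / r;
    return 4.0 * eps * (sr12 - sr6) - ushift + (r - rcut) * fcut;
  }
};

// minimum-image displacement a-b; periodic on all axes except the last
inline void mindisp(const double *a, const double *b, const double *box,
                    int dim, double *out) {
  for (int k = 0; k < dim; ++k) {
    double d = a[k] - b[k];
    if (k < dim - 1) {
      double L = box[k];
      if (d > 0.5 * L) d -= L;
      else if (d < -0.5 * L) d += L;
    }
    out[k] = d;
  }
}

// bonded-pair exclusion table: at most a handful of partners per bead
struct Exclusions {
  std::vector<std::vector<int> > ex;
  Exclusions(int n, const IntegerMatrix &bonds) : ex(n) {
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      ex[i].push_back(j);
      ex[j].push_back(i);
    }
  }
  inline bool excluded(int i, int j) const {
    for (size_t t = 0; t < ex[i].size(); ++t)
      if (ex[i][t] == j) return true;
    return false;
  }
};

class CellList {
 public:
  int dim;
  int nc[3];
  double cw[3];
  std::vector<int> head, nxt;
  bool usable;

  CellList(int dim_, const double *box, double rcut) : dim(dim_) {
    usable = true;
    for (int k = 0; k < dim; ++k) {
      nc[k] = std::max(1, (int)std::floor(box[k] / rcut));
      cw[k] = box[k] / nc[k];
      // periodic axes need >= 3 cells for a correct unique neighbour sweep
      if (k < dim - 1 && nc[k] < 3) usable = false;
      if (k == dim - 1 && nc[k] < 1) usable = false;
    }
  }

  inline int cellIndex(const double *x, const double *box) const {
    int idx = 0;
    for (int k = 0; k < dim; ++k) {
      double xk = x[k];
      if (xk < 0) xk = 0;
      if (xk >= box[k]) xk = box[k] * (1.0 - 1e-12);
      int c = (int)(xk / cw[k]);
      if (c >= nc[k]) c = nc[k] - 1;
      idx = idx * nc[k] + c;
    }
    return idx;
  }

  void build(const NumericMatrix &pos, const double *box) {
    int n = pos.nrow();
    int ncell = 1;
    for (int k = 0; k < dim; ++k) ncell *= nc[k];
    head.assign(ncell, -1);
    nxt.assign(n, -1);
    std::vector<double> x(dim);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < dim; ++k) x[k] = pos(i, k);
      int c = cellIndex(x.data(), box);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// force + potential from the pair interaction; method: 0 = all-pairs,
// 1 = cell list (falls back to all-pairs when the box is too small).
double pairForces(const NumericMatrix &pos, const double *box, int dim,
                  const PairPot &pot, const Exclusions &ex,
                  NumericMatrix &F, int method, double overlap_r2) {
  int n = pos.nrow();
  double pe = 0.0;
  double d[3];
  if (method == 1) {
    CellList cl(dim, box, pot.rcut);
    if (cl.usable) {
      cl.build(pos, box);
      // sweep all neighbour cells of each particle's cell, accumulate the
      // full force on i; each unordered pair is visited twice, so pe * 0.5
      int off[3];
      for (int i = 0; i < n; ++i) {
        double xi[3];
        for (int k = 0; k < dim; ++k) xi[k] = pos(i, k);
        int ci[3];
        {
          int idx = cl.cellIndex(xi, box);
          for (int k = dim - 1; k >= 0; --k) { ci[k] = idx % cl.nc[k]; idx /= cl.nc[k]; }
        }
        int lo2 = (dim == 3) ? -1 : 0, hi2 = (dim == 3) ? 1 : 0;
        for (off[0] = -1; off[0] <= 1; ++off[0])
          for (int o1 = -1; o1 <= 1; ++o1)
            for (int o2 = lo2; o2 <= hi2; ++o2) {
              int cc[3];
              cc[0] = ci[0] + off[0];
              cc[1] = ci[1] + o1;
              cc[2] = (dim == 3) ? ci[2] + o2 : 0;
              // wrap periodic axes; clip the reflective (last) axis
              bool ok = true;
              for (int k = 0; k < dim; ++k) {
                if (k < dim - 1) {
                  if (cc[k] < 0) cc[k] += cl.nc[k];
                  if (cc[k] >= cl.nc[k]) cc[k] -= cl.nc[k];
                } else if (cc[k] < 0 || cc[k] >= cl.nc[k]) ok = false;
              }
              if (dim == 2) { cc[2] = 0; }
              if (!ok) continue;
              // 2D layout: index = c0*nc1 + c1 ; 3D: ((c0*nc1)+c1)*nc2+c2
              int idx = cc[0];
              for (int k = 1; k < dim; ++k) idx = idx * cl.nc[k] + cc[k];
              for (int j = cl.head[idx]; j >= 0; j = cl.nxt[j]) {
                if (j == i) continue;
                double xj[3];
                for (int k = 0; k < dim; ++k) xj[k] = pos(j, k);
                mindisp(xi, xj, box, dim, d);
                double r2 = 0;
                for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
                if (r2 >= pot.rcut2) continue;
                if (ex.excluded(i, j)) continue;
                if (r2 < overlap_r2)
                  stop("particle overlap: pair (%d, %d) at r = %g", i + 1, j + 1,
                       std::sqrt(r2));
                double fr;
                double u = pot.eval(r2, fr);
                pe += 0.5 * u;
                for (int k = 0; k < dim; ++k) F(i, k) += fr * d[k];
              }
            }
      }
      return pe;
    }
    // fall through to all-pairs on unusably small boxes
  }
  for (int i = 0; i < n; ++i) {
    double xi[3];
    for (int k = 0; k < dim; ++k) xi[k] = pos(i, k);
    for (int j = i + 1; j < n; ++j) {
      double xj[3];
      for (int k = 0; k < dim; ++k) xj[k] = pos(j, k);
      mindisp(xi, xj, box, dim, d);
      double r2 = 0;
      for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
      if (r2 >= pot.rcut2) continue;
      if (ex.excluded(i, j)) continue;
      if (r2 < overlap_r2)
        stop("particle overlap: pair (%d, %d) at r = %g", i + 1, j + 1,
             std::sqrt(r2));
      double fr;
      double u = pot.eval(r2, fr);
      pe += u;
      for (int k = 0; k < dim; ++k) {
        F(i, k) += fr * d[k];
        F(j, k) -= fr * d[k];
      }
    }
  }
  return pe;
}

// harmonic bond forces on alive bonds; returns bond potential energy
double bondForces(const NumericMatrix &pos, const double *box, int dim,
                  const IntegerMatrix &bonds, const NumericVector &r0,
                  const NumericVector &kk, const LogicalVector &alive,
                  NumericMatrix &F) {
  double pe = 0.0, d[3];
  for (int b = 0; b < bonds.nrow(); ++b) {
    if (!alive[b]) continue;
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double xi[3], xj[3];
    for (int k = 0; k < dim; ++k) { xi[k] = pos(i, k); xj[k] = pos(j, k); }
    mindisp(xi, xj, box, dim, d);
    double r2 = 0;
    for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
    double r = std::sqrt(r2);
    if (r < 1e-12) stop("bonded pair (%d, %d) at zero separation", i + 1, j + 1);
    double dr = r - r0[b];
    double fmag = -kk[b] * dr / r;     // along d = xi - xj, acting on i
    pe += 0.5 * kk[b] * dr * dr;
    for (int k = 0; k < dim; ++k) {
      F(i, k) += fmag * d[k];
      F(j, k) -= fmag * d[k];
    }
  }
  return pe;
}

double kinetic(const NumericMatrix &vel, const NumericVector &mass, int dim) {
  double ke = 0;
  for (int i = 0; i < vel.nrow(); ++i) {
    double s = 0;
    for (int k = 0; k < dim; ++k) s += vel(i, k) * vel(i, k);
    ke += 0.5 * mass[i] * s;
  }
  return ke;
}

}  // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector box,
                double sigma, double eps, double rcut,
                IntegerMatrix bonds, NumericVector bond_r0,
                NumericVector bond_k, LogicalVector bond_alive,
                int method) {
  int dim = pos.ncol();
  NumericMatrix F(pos.nrow(), dim);
  PairPot pot(sigma, eps, rcut);
  Exclusions ex(pos.nrow(), bonds);
  double overlap_r2 = 0.09 * sigma * sigma;  // 0.3 sigma
  double pe = pairForces(pos, REAL(box), dim, pot, ex, F, method, overlap_r2);
  pe += bondForces(pos, REAL(box), dim, bonds, bond_r0, bond_k, bond_alive, F);
  return List::create(_["forces"] = F, _["pe"] = pe);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos_in, NumericMatrix vel_in, NumericVector mass,
                NumericVector box, double sigma, double eps, double rcut,
                IntegerMatrix bonds, NumericVector bond_r0,
                NumericVector bond_k, NumericVector bond_rbreak,
                LogicalVector bond_alive_in,
                double dt, int nsteps, int stride,
                double thermo_T, double thermo_tau,
                int energy_stride, bool record_frames) {
  int dim = pos_in.ncol(), n = pos_in.nrow();
  NumericMatrix pos = clone(pos_in), vel = clone(vel_in);
  LogicalVector alive = clone(bond_alive_in);
  PairPot pot(sigma, eps, rcut);
  Exclusions ex(n, bonds);
  double overlap_r2 = 0.09 * sigma * sigma;
  const double *B = REAL(box);
  double Lz = B[dim - 1];
  double max_disp = 0.5 * rcut;

  NumericMatrix F(n, dim);
  double pe = pairForces(pos, B, dim, pot, ex, F, 1, overlap_r2);
  pe += bondForces(pos, B, dim, bonds, bond_r0, bond_k, alive, F);
  double sink = 0.0;  // potential energy removed with broken bonds

  List frames;
  std::vector<int> ev_step, ev_bond;
  std::vector<double> en_step, en_ke, en_pe, en_sink;

  double dof = (double)(dim * n);

  if (record_frames) {
    frames.push_back(List::create(_["step"] = 0, _["time"] = 0.0,
                                  _["pos"] = clone(pos), _["vel"] = clone(vel)));
  }
  {
    double ke0 = kinetic(vel, mass, dim);
    en_step.push_back(0); en_ke.push_back(ke0); en_pe.push_back(pe);
    en_sink.push_back(0.0);
  }

  for (int step = 1; step <= nsteps; ++step) {
    // first half-kick + drift
    double vmax2 = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < dim; ++k) {
        vel(i, k) += 0.5 * dt * F(i, k) / mass[i];
        s += vel(i, k) * vel(i, k);
      }
      if (s > vmax2) vmax2 = s;
    }
    if (std::sqrt(vmax2) * dt > max_disp)
      stop("integration unstable at step %d: displacement per step exceeds "
           "half the cutoff; use a smaller timestep", step);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < dim; ++k) pos(i, k) += dt * vel(i, k);
      // periodic wrap on lateral axes
      for (int k = 0; k < dim - 1; ++k) {
        if (pos(i, k) < 0) pos(i, k) += B[k];
        else if (pos(i, k) >= B[k]) pos(i, k) -= B[k];
      }
      // elastic reflection at the shock-axis walls
      double z = pos(i, dim - 1);
      while (z < 0 || z > Lz) {
        if (z < 0) { z = -z; vel(i, dim - 1) = -vel(i, dim - 1); }
        if (z > Lz) { z = 2 * Lz - z; vel(i, dim - 1) = -vel(i, dim - 1); }
      }
      pos(i, dim - 1) = z;
    }
    // new forces + second half-kick
    std::fill(F.begin(), F.end(), 0.0);
    pe = pairForces(pos, B, dim, pot, ex, F, 1, overlap_r2);
    pe += bondForces(pos, B, dim, bonds, bond_r0, bond_k, alive, F);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < dim; ++k)
        vel(i, k) += 0.5 * dt * F(i, k) / mass[i];

    // bond-break check (after the move); all over-stretched bonds break
    for (int b = 0; b < bonds.nrow(); ++b) {
      if (!alive[b]) continue;
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      double d[3], xi[3], xj[3];
      for (int k = 0; k < dim; ++k) { xi[k] = pos(i, k); xj[k] = pos(j, k); }
      mindisp(xi, xj, B, dim, d);
      double r2 = 0;
      for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
      double r = std::sqrt(r2);
      if (r > bond_rbreak[b]) {
        alive[b] = false;
        double dr = r - bond_r0[b];
        sink += 0.5 * bond_k[b] * dr * dr;  // energy ledger for conservation
        pe -= 0.5 * bond_k[b] * dr * dr;
        ev_step.push_back(step);
        ev_bond.push_back(b + 1);
      }
    }

    // weak-coupling thermostat (equilibration only; inert when thermo_T <= 0)
    if (thermo_T > 0) {
      double ke = kinetic(vel, mass, dim);
      double T = 2.0 * ke / dof;
      if (T > 1e-12) {
        double lam = std::sqrt(1.0 + dt / thermo_tau * (thermo_T / T - 1.0));
        if (lam < 0.9) lam = 0.9;
        if (lam > 1.1) lam = 1.1;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < dim; ++k) vel(i, k) *= lam;
      }
      // a fully cold system (T ~ 0) picks up kinetic energy from the jittered
      // lattice potential first; the thermostat engages once T > 0
    }

    if (energy_stride > 0 && (step % energy_stride == 0 || step == nsteps)) {
      en_step.push_back(step);
      en_ke.push_back(kinetic(vel, mass, dim));
      en_pe.push_back(pe);
      en_sink.push_back(sink);
    }
    if (record_frames && (step % stride == 0 || step == nsteps)) {
      frames.push_back(List::create(_["step"] = step, _["time"] = step * dt,
                                    _["pos"] = clone(pos),
                                    _["vel"] = clone(vel)));
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix events(ev_step.size(), 2);
  for (size_t t = 0; t < ev_step.size(); ++t) {
    events(t, 0) = ev_step[t];
    events(t, 1) = ev_bond[t];
  }
  colnames(events) = CharacterVector::create("step", "bond");
  int ne = en_step.size();
  NumericMatrix energy(ne, 4);
  for (int t = 0; t < ne; ++t) {
    energy(t, 0) = en_step[t];
    energy(t, 1) = en_ke[t];
    energy(t, 2) = en_pe[t];
    energy(t, 3) = en_sink[t];
  }
  colnames(energy) = CharacterVector::create("step", "ke", "pe", "sink");
  return List::create(_["pos"] = pos, _["vel"] = vel, _["bond_alive"] = alive,
                      _["frames"] = frames, _["events"] = events,
                      _["energy"] = energy);
}
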