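// Compiled kernels: nonbonded/bonded energies and forces, steepest-descent
// minimization, leap-frog dynamics with CSVR thermostat and weak-coupling
// barostat, group interaction energies, RDF histograms, plain Ewald sum.
//
// Unit system throughout: nm, ps, kJ/mol, K, e, g/mol.  With these units
// acceleration = force/mass comes out directly in nm/ps^2.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double F_COUL = 138.935458;        // kJ mol^-1 nm e^-2
static const double K_BOLTZ = 0.00831446261815324; // kJ mol^-1 K^-1
static const double PRESS_UNIT = 16.6054;       // 1 kJ/mol/nm^3 in bar

struct Box {
  double h[3][3];    // rows are lattice vectors a, b, c
  double hinv[3][3];
  bool diagonal;
  double vol;
};

static Box make_box(const NumericMatrix &m) {
  Box b;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) b.h[i][j] = m(i, j);
  double offd = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) if (i != j) offd += std::fabs(b.h[i][j]);
  b.diagonal = offd < 1e-12;
  const double (*h)[3] = b.h;
  b.vol = h[0][0]*(h[1][1]*h[2][2]-h[1][2]*h[2][1])
        - h[0][1]*(h[1][0]*h[2][2]-h[1][2]*h[2][0])
        + h[0][2]*(h[1][0]*h[2][1]-h[1][1]*h[2][0]);
  if (b.vol <= 0) stop("box has non-positive volume");
  // inverse (for fractional coordinates); h is row-vector convention so
  // s = r %*% hinv with hinv = inverse of h treating vectors as rows.
  double inv[3][3];
  inv[0][0] =  (h[1][1]*h[2][2]-h[1][2]*h[2][1]);
  inv[0][1] = -(h[0][1]*h[2][2]-h[0][2]*h[2][1]);
  inv[0][2] =  (h[0][1]*h[1][2]-h[0][2]*h[1][1]);
  inv[1][0] = -(h[1][0]*h[2][2]-h[1][2]*h[2][0]);
  inv[1][1] =  (h[0][0]*h[2][2]-h[0][2]*h[2][0]);
  inv[1][2] = -(h[0][0]*h[1][2]-h[0][2]*h[1][0]);
  inv[2][0] =  (h[1][0]*h[2][1]-h[1][1]*h[2][0]);
  inv[2][1] = -(h[0][0]*h[2][1]-h[0][1]*h[2][0]);
  inv[2][2] =  (h[0][0]*h[1][1]-h[0][1]*h[1][0]);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) b.hinv[i][j] = inv[j][i] / b.vol; // transpose of cofactor
  return b;
}

// minimum-image displacement r_i - r_j
static inline void mic(const Box &b, double dx[3]) {
  if (b.diagonal) {
    for (int d = 0; d < 3; ++d) {
      double L = b.h[d][d];
      dx[d] -= L * std::round(dx[d] / L);
    }
  } else {
    double s[3];
    for (int d = 0; d < 3; ++d)
      s[d] = dx[0]*b.hinv[0][d] + dx[1]*b.hinv[1][d] + dx[2]*b.hinv[2][d];
    for (int d = 0; d < 3; ++d) s[d] -= std::round(s[d]);
    for (int d = 0; d < 3; ++d)
      dx[d] = s[0]*b.h[0][d] + s[1]*b.h[1][d] + s[2]*b.h[2][d];
  }
}

struct Topo {
  int n;
  std::vector<double> sig, eps, q, mass;
  std::vector<int> molid;
  // exclusions (1-2, 1-3 and 1-4) as per-atom sorted neighbour lists
  std::vector<std::vector<int>> excl;
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_th0, a_kth;
  std::vector<int> p14_i, p14_j;
  double f14_lj, f14_coul;
};

static Topo make_topo(const List &top) {
  Topo t;
  NumericVector sig = top["sigma"], eps = top["epsilon"], q = top["charge"],
                mass = top["mass"];
  t.n = sig.size();
  t.sig.assign(sig.begin(), sig.end());
  t.eps.assign(eps.begin(), eps.end());
  t.q.assign(q.begin(), q.end());
  t.mass.assign(mass.begin(), mass.end());
  IntegerVector mol = top["molid"];
  t.molid.assign(mol.begin(), mol.end());
  t.excl.resize(t.n);
  IntegerMatrix ex = top["exclusions"];  // 0-based, includes 1-4 pairs
  for (int r = 0; r < ex.nrow(); ++r) {
    int i = ex(r, 0), j = ex(r, 1);
    t.excl[i].push_back(j);
    t.excl[j].push_back(i);
  }
  for (int i = 0; i < t.n; ++i) std::sort(t.excl[i].begin(), t.excl[i].end());
  NumericMatrix bd = top["bonds"]; // cols: i j r0 k (0-based indices)
  for (int r = 0; r < bd.nrow(); ++r) {
    t.b_i.push_back((int)bd(r,0)); t.b_j.push_back((int)bd(r,1));
    t.b_r0.push_back(bd(r,2)); t.b_k.push_back(bd(r,3));
  }
  NumericMatrix an = top["angles"]; // i j k theta0(rad) ktheta
  for (int r = 0; r < an.nrow(); ++r) {
    t.a_i.push_back((int)an(r,0)); t.a_j.push_back((int)an(r,1));
    t.a_k.push_back((int)an(r,2));
    t.a_th0.push_back(an(r,3)); t.a_kth.push_back(an(r,4));
  }
  IntegerMatrix p14 = top["pairs14"];
  for (int r = 0; r < p14.nrow(); ++r) {
    t.p14_i.push_back(p14(r,0)); t.p14_j.push_back(p14(r,1));
  }
  t.f14_lj = as<double>(top["f14_lj"]);
  t.f14_coul = as<double>(top["f14_coul"]);
  return t;
}

static inline bool is_excluded(const Topo &t, int i, int j) {
  if (t.molid[i] != t.molid[j]) return false; // exclusions are intramolecular
  const std::vector<int> &e = t.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

struct NbOpts {
  double rc_lj, rc_coul, rc_max;
  bool shift_lj, shift_coul;
  bool use_cells;
  double disp_corr; // 0 = off
};

struct EnerAcc {
  double elj = 0, ecoul = 0, ebond = 0, eangle = 0, e14 = 0;
  double virial = 0;
};

// one nonbonded pair; fx accumulated for atom i (atom j gets -f)
static inline void nb_pair(const Topo &t, const NbOpts &o,
                           int i, int j, const double dx[3], double r2,
                           EnerAcc &E, double *fi, double *fj, bool do_force,
                           double scale_lj, double scale_coul) {
  double r = std::sqrt(r2);
  double fcoef = 0.0;
  if (scale_lj > 0 && r <= o.rc_lj && t.eps[i] > 0 && t.eps[j] > 0) {
    double sij = std::sqrt(t.sig[i] * t.sig[j]);
    double eij = std::sqrt(t.eps[i] * t.eps[j]);
    double sr2 = sij * sij / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    double e = 4.0 * eij * (sr12 - sr6);
    if (o.shift_lj) {
      double src2 = sij * sij / (o.rc_lj * o.rc_lj);
      double src6 = src2 * src2 * src2;
      e -= 4.0 * eij * (src6 * src6 - src6);
    }
    E.elj += scale_lj * e;
    if (do_force) fcoef += scale_lj * (48.0 * eij * sr12 - 24.0 * eij * sr6) / r2;
  }
  if (scale_coul > 0 && r <= o.rc_coul) {
    double qq = t.q[i] * t.q[j];
    if (qq != 0.0) {
      double e = F_COUL * qq / r;
      if (o.shift_coul) e -= F_COUL * qq / o.rc_coul;
      E.ecoul += scale_coul * e;
      if (do_force) fcoef += scale_coul * F_COUL * qq / (r2 * r);
    }
  }
  if (do_force && fcoef != 0.0) {
    for (int d = 0; d < 3; ++d) {
      double f = fcoef * dx[d];
      fi[d] += f;
      fj[d] -= f;
    }
    E.virial += fcoef * r2;
  } else if (fcoef != 0.0) {
    E.virial += fcoef * r2;
  }
}

static void bonded_forces(const Topo &t, const Box &box,
                          const std::vector<double> &x,
                          EnerAcc &E, std::vector<double> &f, bool do_force) {
  // harmonic bonds, E = 0.5 k (r - r0)^2
  for (size_t b = 0; b < t.b_i.size(); ++b) {
    int i = t.b_i[b], j = t.b_j[b];
    double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    mic(box, dx);
    double r = std::sqrt(dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2]);
    double dr = r - t.b_r0[b];
    E.ebond += 0.5 * t.b_k[b] * dr * dr;
    if (do_force && r > 1e-12) {
      double fcoef = -t.b_k[b] * dr / r;
      for (int d = 0; d < 3; ++d) {
        f[3*i+d] += fcoef * dx[d];
        f[3*j+d] -= fcoef * dx[d];
      }
      E.virial += fcoef * r * r;
    }
  }
  // harmonic angles, E = 0.5 k (theta - theta0)^2
  for (size_t a = 0; a < t.a_i.size(); ++a) {
    int i = t.a_i[a], j = t.a_j[a], k = t.a_k[a];
    double rij[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    double rkj[3] = { x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2] };
    mic(box, rij); mic(box, rkj);
    double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    if (nij < 1e-12 || nkj < 1e-12) continue;
    double cth = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij*nkj);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - t.a_th0[a];
    E.eangle += 0.5 * t.a_kth[a] * dth * dth;
    if (do_force) {
      double sth = std::sqrt(1.0 - cth*cth);
      if (sth < 1e-8) sth = 1e-8;
      // F_i = -dE/dx_i = +k (theta - theta0)/sin(theta) * dcos/dx_i
      double coef = t.a_kth[a] * dth / sth;
      for (int d = 0; d < 3; ++d) {
        double dcos_di = (rkj[d]/(nij*nkj)) - cth*rij[d]/(nij*nij);
        double dcos_dk = (rij[d]/(nij*nkj)) - cth*rkj[d]/(nkj*nkj);
        double fi = coef * dcos_di;
        double fk = coef * dcos_dk;
        f[3*i+d] += fi;
        f[3*k+d] += fk;
        f[3*j+d] -= (fi + fk);
      }
    }
  }
  // scaled 1-4 pairs: LJ + Coulomb, unshifted (always inside cutoff range)
  // handled by caller via nb_pair with scaling to reuse geometry code
}

struct PairList {
  std::vector<int> pi, pj;
  std::vector<double> x_ref; // positions at build time
  double r_list = 0;         // cutoff + skin used at build
  bool built = false;
};

// build all non-excluded pairs within r_list (cell binning when possible)
static void build_pairs(const Topo &t, const Box &box, const NbOpts &o,
                        const std::vector<double> &x, double skin,
                        PairList &pl) {
  int n = t.n;
  pl.pi.clear(); pl.pj.clear();
  pl.r_list = o.rc_max + skin;
  double rl2 = pl.r_list * pl.r_list;
  auto consider = [&](int i, int j) {
    if (is_excluded(t, i, j)) return;
    double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    mic(box, dx);
    double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
    if (r2 <= rl2) { pl.pi.push_back(i); pl.pj.push_back(j); }
  };
  bool cells_ok = o.use_cells && box.diagonal;
  int nc[3] = {0,0,0};
  if (cells_ok) {
    for (int d = 0; d < 3; ++d) {
      nc[d] = (int)std::floor(box.h[d][d] / pl.r_list);
      if (nc[d] < 3) { cells_ok = false; break; }
    }
  }
  if (!cells_ok) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  } else {
    int ncells = nc[0]*nc[1]*nc[2];
    std::vector<int> head(ncells, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double L = box.h[d][d];
        double xi = x[3*i+d] - L * std::floor(x[3*i+d] / L);
        c[d] = (int)(xi / (L / nc[d]));
        if (c[d] >= nc[d]) c[d] = nc[d]-1;
        if (c[d] < 0) c[d] = 0;
      }
      int cc = (c[2]*nc[1] + c[1])*nc[0] + c[0];
      nxt[i] = head[cc];
      head[cc] = i;
    }
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int cc = (cz*nc[1] + cy)*nc[0] + cx;
          for (int i = head[cc]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j]) consider(i, j);
          for (int s = 0; s < 13; ++s) {
            int ox = (cx + off[s][0] + nc[0]) % nc[0];
            int oy = (cy + off[s][1] + nc[1]) % nc[1];
            int oz = (cz + off[s][2] + nc[2]) % nc[2];
            int co = (oz*nc[1] + oy)*nc[0] + ox;
            if (co == cc) continue;
            for (int i = head[cc]; i >= 0; i = nxt[i])
              for (int j = head[co]; j >= 0; j = nxt[j]) consider(i, j);
          }
        }
  }
  pl.x_ref = x;
  pl.built = true;
}

// largest atomic displacement since the list was built
static double max_displacement(const Box &box, const std::vector<double> &x,
                               const std::vector<double> &x_ref) {
  double m2 = 0;
  int n = (int)x.size() / 3;
  for (int i = 0; i < n; ++i) {
    double dx[3] = { x[3*i]-x_ref[3*i], x[3*i+1]-x_ref[3*i+1],
                     x[3*i+2]-x_ref[3*i+2] };
    double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
    if (r2 > m2) m2 = r2;
  }
  return std::sqrt(m2);
}

static void compute_all(const Topo &t, const Box &box, const NbOpts &o,
                        const std::vector<double> &x,
                        EnerAcc &E, std::vector<double> &f, bool do_force,
                        PairList *pl = nullptr) {
  int n = t.n;
  if (do_force) std::fill(f.begin(), f.end(), 0.0);
  PairList local;
  if (pl == nullptr) {
    build_pairs(t, box, o, x, 0.0, local);
    pl = &local;
  }
  double rc2 = o.rc_max * o.rc_max;
  size_t np = pl->pi.size();
  for (size_t p = 0; p < np; ++p) {
    int i = pl->pi[p], j = pl->pj[p];
    double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    mic(box, dx);
    double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
    if (r2 <= rc2 && r2 > 0)
      nb_pair(t, o, i, j, dx, r2, E,
              do_force ? &f[3*i] : nullptr,
              do_force ? &f[3*j] : nullptr, do_force, 1.0, 1.0);
  }
  // 1-4 pairs, scaled, no cutoff shift (geometrically always well inside rc)
  NbOpts o14 = o;
  o14.shift_lj = false; o14.shift_coul = false;
  for (size_t p = 0; p < t.p14_i.size(); ++p) {
    int i = t.p14_i[p], j = t.p14_j[p];
    double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    mic(box, dx);
    double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
    if (r2 <= rc2 && r2 > 0) {
      EnerAcc E14;
      nb_pair(t, o14, i, j, dx, r2, E14,
              do_force ? &f[3*i] : nullptr,
              do_force ? &f[3*j] : nullptr, do_force,
              t.f14_lj, t.f14_coul);
      E.elj += E14.elj; E.ecoul += E14.ecoul; E.virial += E14.virial;
    }
  }
  bonded_forces(t, box, x, E, f, do_force);
  if (o.disp_corr > 0) E.elj += o.disp_corr; // precomputed homogeneous tail
}

static NbOpts make_opts(const List &opts) {
  NbOpts o;
  o.rc_lj = as<double>(opts["rc_lj"]);
  o.rc_coul = as<double>(opts["rc_coul"]);
  o.rc_max = std::max(o.rc_lj, o.rc_coul);
  o.shift_lj = as<bool>(opts["shift_lj"]);
  o.shift_coul = as<bool>(opts["shift_coul"]);
  o.use_cells = as<bool>(opts["use_cells"]);
  o.disp_corr = opts.containsElementNamed("disp_corr")
                ? as<double>(opts["disp_corr"]) : 0.0;
  return o;
}

static void check_box_cutoff(const Box &b, const NbOpts &o) {
  // minimum image needs every perpendicular box width >= 2 rc
  double w[3];
  if (b.diagonal) {
    for (int d = 0; d < 3; ++d) w[d] = b.h[d][d];
  } else {
    // width along each reciprocal direction = V / |cross of other two rows|
    for (int d = 0; d < 3; ++d) {
      int u = (d+1)%3, v = (d+2)%3;
      double cx = b.h[u][1]*b.h[v][2]-b.h[u][2]*b.h[v][1];
      double cy = b.h[u][2]*b.h[v][0]-b.h[u][0]*b.h[v][2];
      double cz = b.h[u][0]*b.h[v][1]-b.h[u][1]*b.h[v][0];
      w[d] = b.vol / std::sqrt(cx*cx+cy*cy+cz*cz);
    }
  }
  for (int d = 0; d < 3; ++d)
    if (w[d] < 2.0 * o.rc_max)
      stop("box dimension %f nm is smaller than twice the cutoff (%f nm); minimum image invalid",
           w[d], o.rc_max);
}

// [[Rcpp::export]]
List cpp_potential(NumericMatrix pos, NumericMatrix boxmat, List top, List opts,
                   bool forces = false) {
  Box box = make_box(boxmat);
  Topo t = make_topo(top);
  NbOpts o = make_opts(opts);
  check_box_cutoff(box, o);
  int n = pos.nrow();
  if (n != t.n) stop("position/topology atom count mismatch");
  std::vector<double> x(3*n), f(3*n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i,d);
  EnerAcc E;
  compute_all(t, box, o, x, E, f, forces);
  List out = List::create(
    _["e_lj"] = E.elj, _["e_coul"] = E.ecoul,
    _["e_bond"] = E.ebond, _["e_angle"] = E.eangle,
    _["e_bonded"] = E.ebond + E.eangle,
    _["virial"] = E.virial, _["volume"] = box.vol);
  if (forces) {
    NumericMatrix fm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fm(i,d) = f[3*i+d];
    out["forces"] = fm;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, NumericMatrix boxmat, List top, List opts,
                  double ftol, int max_steps, double step0) {
  Box box = make_box(boxmat);
  Topo t = make_topo(top);
  NbOpts o = make_opts(opts);
  check_box_cutoff(box, o);
  int n = pos.nrow();
  std::vector<double> x(3*n), f(3*n), xt(3*n), ft(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i,d);
  EnerAcc E;
  compute_all(t, box, o, x, E, f, true);
  double e = E.elj + E.ecoul + E.ebond + E.eangle;
  if (!std::isfinite(e))
    stop("non-finite starting energy: overlapping atoms?");
  auto maxforce = [&](const std::vector<double> &fv) {
    double m = 0;
    for (int i = 0; i < n; ++i) {
      double f2 = fv[3*i]*fv[3*i]+fv[3*i+1]*fv[3*i+1]+fv[3*i+2]*fv[3*i+2];
      if (f2 > m) m = f2;
    }
    return std::sqrt(m);
  };
  double h = step0;
  double fmax = maxforce(f);
  int steps = 0;
  bool converged = fmax <= ftol;
  while (!converged && steps < max_steps && h > 1e-10) {
    double scale = h / fmax;
    for (int i = 0; i < 3*n; ++i) xt[i] = x[i] + scale * f[i];
    EnerAcc Et;
    compute_all(t, box, o, xt, Et, ft, true);
    double et = Et.elj + Et.ecoul + Et.ebond + Et.eangle;
    if (std::isfinite(et) && et < e) {
      x = xt; f = ft; e = et;
      fmax = maxforce(f);
      h *= 1.2;
      converged = fmax <= ftol;
    } else {
      h *= 0.5;
    }
    ++steps;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i,d) = x[3*i+d];
  return List::create(_["positions"] = out, _["energy"] = e,
                      _["max_force"] = fmax, _["steps"] = steps,
                      _["converged"] = converged);
}

// canonical stochastic velocity rescale (CSVR) scale factor alpha^2
static double csvr_alpha2(double K, double Kbar, int nf, double c) {
  // c = exp(-dt/tau); R1 standard normal; S ~ chi^2_{nf-1}
  double R1 = R::norm_rand();
  double S = (nf > 1) ? R::rchisq((double)(nf - 1)) : 0.0;
  double a2 = c + (1.0 - c) * (S + R1 * R1) * Kbar / (nf * K)
              + 2.0 * R1 * std::sqrt(c * (1.0 - c) * Kbar / (nf * K));
  return a2;
}

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix pos, NumericMatrix vel, NumericMatrix boxmat,
                   List top, List opts,
                   double dt, int n_steps, int save_every,
                   bool thermostat, double target_T, double tau_t,
                   int thermostat_type, // 0 = CSVR, 1 = Berendsen
                   bool barostat, double target_P, double tau_p,
                   double compressibility,
                   bool remove_com, double t0) {
  Box box = make_box(boxmat);
  Topo t = make_topo(top);
  NbOpts o = make_opts(opts);
  check_box_cutoff(box, o);
  int n = pos.nrow();
  if (barostat && !box.diagonal)
    stop("isotropic barostat requires an orthorhombic box");
  std::vector<double> x(3*n), v(3*n), f(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3*i+d] = pos(i,d); v[3*i+d] = vel(i,d); }
  int nf = 3 * n - 3;
  if (nf < 1) nf = 3 * n;
  double Kbar = 0.5 * nf * K_BOLTZ * target_T;
  double c_t = std::exp(-dt / tau_t);

  int n_save = n_steps / save_every + 1;
  List frames_pos(n_save), frames_vel(n_save), frames_box(n_save);
  NumericMatrix ener(n_save, 10);
  colnames(ener) = CharacterVector::create(
    "time","e_kin","e_pot","e_coul","e_lj","e_bonded","e_total",
    "temperature","pressure","volume");

  const double skin = 0.2; // nm; rebuild when any displacement > skin/2
  PairList pl;
  build_pairs(t, box, o, x, skin, pl);
  EnerAcc E;
  compute_all(t, box, o, x, E, f, true, &pl);

  auto kinetic = [&](const std::vector<double> &vv) {
    double K = 0;
    for (int i = 0; i < n; ++i)
      K += 0.5 * t.mass[i] * (vv[3*i]*vv[3*i]+vv[3*i+1]*vv[3*i+1]+vv[3*i+2]*vv[3*i+2]);
    return K;
  };
  auto remove_com_v = [&](std::vector<double> &vv) {
    double p[3] = {0,0,0}, M = 0;
    for (int i = 0; i < n; ++i) {
      M += t.mass[i];
      for (int d = 0; d < 3; ++d) p[d] += t.mass[i] * vv[3*i+d];
    }
    for (int d = 0; d < 3; ++d) p[d] /= M;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) vv[3*i+d] -= p[d];
  };

  // full-step kinetic energy: average of the two adjacent half-step KEs
  // (leap-frog velocities live at t -/+ dt/2); removes the O(dt^2) bias
  double ke_report = kinetic(v);
  auto save_frame = [&](int slot, int step) {
    NumericMatrix pm(n, 3), vm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) { pm(i,d) = x[3*i+d]; vm(i,d) = v[3*i+d]; }
    NumericMatrix bm(3, 3);
    for (int a = 0; a < 3; ++a)
      for (int b2 = 0; b2 < 3; ++b2) bm(a,b2) = box.h[a][b2];
    frames_pos[slot] = pm; frames_vel[slot] = vm; frames_box[slot] = bm;
    double K = ke_report;
    double epot = E.elj + E.ecoul + E.ebond + E.eangle;
    double P = (2.0 * K + E.virial) / (3.0 * box.vol) * PRESS_UNIT;
    ener(slot, 0) = t0 + step * dt;
    ener(slot, 1) = K;
    ener(slot, 2) = epot;
    ener(slot, 3) = E.ecoul;
    ener(slot, 4) = E.elj;
    ener(slot, 5) = E.ebond + E.eangle;
    ener(slot, 6) = K + epot;
    ener(slot, 7) = 2.0 * K / (nf * K_BOLTZ);
    ener(slot, 8) = P;
    ener(slot, 9) = box.vol;
  };

  save_frame(0, 0);
  int slot = 1;
  for (int step = 1; step <= n_steps; ++step) {
    double ke_before = kinetic(v);
    // leap-frog: v(t+dt/2) = v(t-dt/2) + dt f(t)/m ; x(t+dt) = x(t) + dt v
    for (int i = 0; i < n; ++i) {
      double im = dt / t.mass[i];
      for (int d = 0; d < 3; ++d) v[3*i+d] += im * f[3*i+d];
    }
    if (remove_com) remove_com_v(v);
    if (thermostat) {
      double K = kinetic(v);
      if (K > 1e-12) {
        double a2;
        if (thermostat_type == 0) {
          a2 = csvr_alpha2(K, Kbar, nf, c_t);
        } else { // Berendsen
          a2 = 1.0 + (dt / tau_t) * (Kbar / K - 1.0);
        }
        if (a2 < 0) a2 = 0;
        double a = std::sqrt(a2);
        for (int i = 0; i < 3*n; ++i) v[i] *= a;
      }
    }
    ke_report = 0.5 * (ke_before + kinetic(v));
    for (int i = 0; i < 3*n; ++i) x[i] += dt * v[i];
    if (barostat) {
      double K = kinetic(v);
      double P = (2.0 * K + E.virial) / (3.0 * box.vol) * PRESS_UNIT;
      // weak coupling: mu^3 = 1 - beta_T (dt/tau_P) (P0 - P)
      double mu = std::cbrt(1.0 - compressibility * (dt / tau_p) * (target_P - P));
      if (!(mu > 0)) stop("barostat produced non-positive box scaling");
      for (int d = 0; d < 3; ++d) box.h[d][d] *= mu;
      box = [&]{ NumericMatrix bm(3,3);
        for (int a=0;a<3;++a) for (int b2=0;b2<3;++b2) bm(a,b2)=box.h[a][b2];
        return make_box(bm); }();
      for (int i = 0; i < 3*n; ++i) x[i] *= mu;
      check_box_cutoff(box, o);
    }
    if (barostat || max_displacement(box, x, pl.x_ref) > skin / 2)
      build_pairs(t, box, o, x, skin, pl);
    E = EnerAcc();
    compute_all(t, box, o, x, E, f, true, &pl);
    double epot = E.elj + E.ecoul + E.ebond + E.eangle;
    if (!std::isfinite(epot) || std::fabs(epot) > 1e6 * n)
      stop("energy divergence at step %d (E_pot = %g kJ/mol); reduce dt or minimize first",
           step, epot);
    if (step % save_every == 0) { save_frame(slot, step); ++slot; }
  }
  return List::create(_["positions"] = frames_pos, _["velocities"] = frames_vel,
                      _["boxes"] = frames_box, _["energies"] = ener,
                      _["dt"] = dt, _["save_every"] = save_every);
}

// interaction energy between two atom groups (0-based indices)
// [[Rcpp::export]]
NumericVector cpp_group_energy(NumericMatrix pos, NumericMatrix boxmat,
                               List top, List opts,
                               IntegerVector idx_a, IntegerVector idx_b,
                               bool same_group,
                               IntegerVector molid, bool exclude_same_mol) {
  Box box = make_box(boxmat);
  Topo t = make_topo(top);
  NbOpts o = make_opts(opts);
  check_box_cutoff(box, o);
  int n = pos.nrow();
  std::vector<double> x(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i,d);
  double rc2 = o.rc_max * o.rc_max;
  EnerAcc E;
  auto do_pair = [&](int i, int j) {
    if (i == j) return;
    if (exclude_same_mol && molid[i] == molid[j]) return;
    if (is_excluded(t, i, j)) return;
    double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    mic(box, dx);
    double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
    if (r2 <= rc2 && r2 > 0)
      nb_pair(t, o, i, j, dx, r2, E, nullptr, nullptr, false, 1.0, 1.0);
  };
  if (same_group) {
    for (int a = 0; a < idx_a.size(); ++a)
      for (int b = a + 1; b < idx_a.size(); ++b)
        do_pair(idx_a[a], idx_a[b]);
  } else {
    for (int a = 0; a < idx_a.size(); ++a)
      for (int b = 0; b < idx_b.size(); ++b)
        do_pair(idx_a[a], idx_b[b]);
  }
  return NumericVector::create(_["e_coul"] = E.ecoul, _["e_lj"] = E.elj);
}

// ordered-pair distance histogram for g(r): counts j around i
// [[Rcpp::export]]
IntegerVector cpp_rdf_hist(NumericMatrix pos, NumericMatrix boxmat,
                           IntegerVector idx_i, IntegerVector idx_j,
                           double r_max, double dr,
                           IntegerVector molid, bool exclude_same_mol) {
  Box box = make_box(boxmat);
  int nb = (int)std::ceil(r_max / dr);
  IntegerVector h(nb);
  int n = pos.nrow();
  std::vector<double> x(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i,d);
  double rm2 = r_max * r_max;
  for (int a = 0; a < idx_i.size(); ++a) {
    int i = idx_i[a];
    for (int b = 0; b < idx_j.size(); ++b) {
      int j = idx_j[b];
      if (i == j) continue;
      if (exclude_same_mol && molid[i] == molid[j]) continue;
      double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
      mic(box, dx);
      double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
      if (r2 < rm2) {
        int bin = (int)(std::sqrt(r2) / dr);
        if (bin >= 0 && bin < nb) ++h[bin];
      }
    }
  }
  return h;
}

// plain Ewald sum (real + reciprocal + self), energy only, small systems
// [[Rcpp::export]]
double cpp_ewald_energy(NumericMatrix pos, NumericMatrix boxmat,
                        NumericVector q, double alpha, int kmax,
                        double r_cut) {
  Box box = make_box(boxmat);
  if (!box.diagonal) stop("plain Ewald implemented for orthorhombic boxes only");
  int n = pos.nrow();
  if (n > 3000) stop("plain Ewald limited to <= 3000 atoms");
  double L[3] = { box.h[0][0], box.h[1][1], box.h[2][2] };
  std::vector<double> x(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i,d);
  // real space
  double e_real = 0;
  double rc2 = r_cut * r_cut;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
      mic(box, dx);
      double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
      if (r2 <= rc2 && r2 > 0) {
        double r = std::sqrt(r2);
        e_real += q[i]*q[j]*std::erfc(alpha*r)/r;
      }
    }
  // reciprocal space
  double e_rec = 0;
  const double twopi = 2.0 * M_PI;
  for (int kx = -kmax; kx <= kmax; ++kx)
    for (int ky = -kmax; ky <= kmax; ++ky)
      for (int kz = -kmax; kz <= kmax; ++kz) {
        if (kx == 0 && ky == 0 && kz == 0) continue;
        double k[3] = { twopi*kx/L[0], twopi*ky/L[1], twopi*kz/L[2] };
        double k2 = k[0]*k[0]+k[1]*k[1]+k[2]*k[2];
        double sr = 0, si = 0;
        for (int i = 0; i < n; ++i) {
          double kr = k[0]*x[3*i]+k[1]*x[3*i+1]+k[2]*x[3*i+2];
          sr += q[i]*std::cos(kr);
          si += q[i]*std::sin(kr);
        }
        e_rec += std::exp(-k2/(4*alpha*alpha))/k2*(sr*sr+si*si);
      }
  e_rec *= twopi / (L[0]*L[1]*L[2]);
  // self energy
  double e_self = 0;
  for (int i = 0; i < n; ++i) e_self += q[i]*q[i];
  e_self *= -alpha / std::sqrt(M_PI);
  return F_COUL * (e_real + e_rec + e_self);
}
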