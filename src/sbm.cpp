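// Energy/force kernel for single- and dual-basin structure-based models,
// plus a BAOAB Langevin integrator in reduced units (all masses 1).
#include <RcppArmadillo.h>
#include <unordered_set>
#include <random>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Topo {
  int n;
  std::vector<int> bi, bj; std::vector<double> b0, kb;
  std::vector<int> ai, aj, ak; std::vector<double> th0, ka;
  std::vector<int> di, dj, dk, dl; std::vector<double> p0a, p0b, kd;
  std::vector<bool> ddual;
  std::vector<int> ci, cj; std::vector<double> r0a, r0b, sig, rex, eps;
  std::vector<bool> cdual;
  std::unordered_set<long long> excl; // nonbonded exclusions (incl. contacts)
  double rnn, rcut;
};

static inline long long pk(int i, int j, int n) {
  return (long long)std::min(i, j) * n + std::max(i, j);
}

static Topo parse_topo(const List& tl) {
  Topo t;
  t.n = as<int>(tl["n"]);
  IntegerVector bi = tl["bi"], bj = tl["bj"];
  NumericVector b0 = tl["b0"], kb = tl["kb"];
  for (int r = 0; r < bi.size(); ++r) {
    t.bi.push_back(bi[r]-1); t.bj.push_back(bj[r]-1);
    t.b0.push_back(b0[r]); t.kb.push_back(kb[r]);
  }
  IntegerVector ai = tl["ai"], aj = tl["aj"], ak = tl["ak"];
  NumericVector th0 = tl["th0"], ka = tl["ka"];
  for (int r = 0; r < ai.size(); ++r) {
    t.ai.push_back(ai[r]-1); t.aj.push_back(aj[r]-1); t.ak.push_back(ak[r]-1);
    t.th0.push_back(th0[r]); t.ka.push_back(ka[r]);
  }
  IntegerVector di = tl["di"], dj = tl["dj"], dk = tl["dk"], dl = tl["dl"];
  NumericVector p0a = tl["p0a"], p0b = tl["p0b"], kd = tl["kd"];
  for (int r = 0; r < di.size(); ++r) {
    t.di.push_back(di[r]-1); t.dj.push_back(dj[r]-1);
    t.dk.push_back(dk[r]-1); t.dl.push_back(dl[r]-1);
    t.p0a.push_back(p0a[r]);
    bool dual = !NumericVector::is_na(p0b[r]);
    t.p0b.push_back(dual ? p0b[r] : 0.0);
    t.ddual.push_back(dual);
    t.kd.push_back(kd[r]);
  }
  IntegerVector ci = tl["ci"], cj = tl["cj"];
  NumericVector r0a = tl["r0a"], r0b = tl["r0b"], sig = tl["sig"],
    rex = tl["rex"], eps = tl["eps"];
  for (int r = 0; r < ci.size(); ++r) {
    t.ci.push_back(ci[r]-1); t.cj.push_back(cj[r]-1);
    t.r0a.push_back(r0a[r]);
    bool dual = !NumericVector::is_na(r0b[r]);
    t.r0b.push_back(dual ? r0b[r] : 0.0);
    t.cdual.push_back(dual);
    t.sig.push_back(sig[r]); t.rex.push_back(rex[r]); t.eps.push_back(eps[r]);
  }
  IntegerVector ei = tl["ei"], ej = tl["ej"];
  for (int r = 0; r < ei.size(); ++r) t.excl.insert(pk(ei[r]-1, ej[r]-1, t.n));
  t.rnn = as<double>(tl["r_nn"]);
  t.rcut = as<double>(tl["nn_rcut"]);
  return t;
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Dihedral V = kd [ (1 - cos D) + 0.5 (1 - cos 3D) ], D = phi - phi0.
static inline double dih_v(double d, double kd) {
  return kd * ((1.0 - std::cos(d)) + 0.5 * (1.0 - std::cos(3.0 * d)));
}
static inline double dih_dv(double d, double kd) {
  return kd * (std::sin(d) + 1.5 * std::sin(3.0 * d));
}

// Evaluate energies and forces; nn = nonbonded candidate pair list.
// Scalar kernel (no vector temporaries: this runs ~10^6 times per
// trajectory). Column pointers into the n x 3 coordinate/force matrices.
static void eval_ef(const Topo& t, const arma::mat& x, arma::mat& f,
                    const std::vector<std::pair<int,int>>& nn, double* e) {
  f.zeros();
  const double *X = x.colptr(0), *Y = x.colptr(1), *Z = x.colptr(2);
  double *FX = f.colptr(0), *FY = f.colptr(1), *FZ = f.colptr(2);
  double eb = 0, ea = 0, ed = 0, ec = 0, er = 0;
  // bonds
  for (size_t r = 0; r < t.bi.size(); ++r) {
    int i = t.bi[r], j = t.bj[r];
    double dx = X[j]-X[i], dy = Y[j]-Y[i], dz = Z[j]-Z[i];
    double rr = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dev = rr - t.b0[r];
    eb += 0.5 * t.kb[r] * dev * dev;
    double s = t.kb[r] * dev / rr;
    FX[i] += s*dx; FY[i] += s*dy; FZ[i] += s*dz;
    FX[j] -= s*dx; FY[j] -= s*dy; FZ[j] -= s*dz;
  }
  // angles
  for (size_t r = 0; r < t.ai.size(); ++r) {
    int i = t.ai[r], j = t.aj[r], k = t.ak[r];
    double ux = X[i]-X[j], uy = Y[i]-Y[j], uz = Z[i]-Z[j];
    double wx = X[k]-X[j], wy = Y[k]-Y[j], wz = Z[k]-Z[j];
    double ru2 = ux*ux+uy*uy+uz*uz, rw2 = wx*wx+wy*wy+wz*wz;
    double ru = std::sqrt(ru2), rw = std::sqrt(rw2);
    double c = (ux*wx+uy*wy+uz*wz) / (ru*rw);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double s = std::sqrt(std::max(1e-12, 1.0 - c*c));
    double dv = t.ka[r] * (th - t.th0[r]);
    ea += 0.5 * t.ka[r] * (th - t.th0[r]) * (th - t.th0[r]);
    double g = dv / s, iurw = 1.0/(ru*rw);
    double fix = g*(wx*iurw - c*ux/ru2), fiy = g*(wy*iurw - c*uy/ru2),
           fiz = g*(wz*iurw - c*uz/ru2);
    double fkx = g*(ux*iurw - c*wx/rw2), fky = g*(uy*iurw - c*wy/rw2),
           fkz = g*(uz*iurw - c*wz/rw2);
    FX[i] += fix; FY[i] += fiy; FZ[i] += fiz;
    FX[k] += fkx; FY[k] += fky; FZ[k] += fkz;
    FX[j] -= fix+fkx; FY[j] -= fiy+fky; FZ[j] -= fiz+fkz;
  }
  // proper dihedrals (single- or two-well)
  for (size_t r = 0; r < t.di.size(); ++r) {
    int i = t.di[r], j = t.dj[r], k = t.dk[r], l = t.dl[r];
    double b1x = X[j]-X[i], b1y = Y[j]-Y[i], b1z = Z[j]-Z[i];
    double b2x = X[k]-X[j], b2y = Y[k]-Y[j], b2z = Z[k]-Z[j];
    double b3x = X[l]-X[k], b3y = Y[l]-Y[k], b3z = Z[l]-Z[k];
    double mx = b1y*b2z-b1z*b2y, my = b1z*b2x-b1x*b2z, mz = b1x*b2y-b1y*b2x;
    double nx = b2y*b3z-b2z*b3y, ny = b2z*b3x-b2x*b3z, nz = b2x*b3y-b2y*b3x;
    double rb2 = std::sqrt(b2x*b2x+b2y*b2y+b2z*b2z);
    double cx = my*nz-mz*ny, cy = mz*nx-mx*nz, cz = mx*ny-my*nx;
    double phi = std::atan2((cx*b2x+cy*b2y+cz*b2z)/rb2,
                            mx*nx+my*ny+mz*nz);
    double dv, ev;
    if (t.ddual[r]) {
      double da = wrap_pi(phi - t.p0a[r]), db = wrap_pi(phi - t.p0b[r]);
      ev = 0.5 * (dih_v(da, t.kd[r]) + dih_v(db, t.kd[r]));
      dv = 0.5 * (dih_dv(da, t.kd[r]) + dih_dv(db, t.kd[r]));
    } else {
      double da = wrap_pi(phi - t.p0a[r]);
      ev = dih_v(da, t.kd[r]); dv = dih_dv(da, t.kd[r]);
    }
    ed += ev;
    // Floor |m|^2 / |n|^2: the torsion gradient diverges when three of
    // the four atoms go collinear, which transiently happens in
    // bead-chain models during torsion flips; the floor caps the force
    // while leaving regular geometries untouched.
    double m2 = std::max(mx*mx+my*my+mz*mz, 1e-5);
    double n2 = std::max(nx*nx+ny*ny+nz*nz, 1e-5);
    // dphi/dx for the four atoms (numerically verified forms)
    double gi = -rb2/m2, gl = rb2/n2;
    double tix = gi*mx, tiy = gi*my, tiz = gi*mz;
    double tlx = gl*nx, tly = gl*ny, tlz = gl*nz;
    double pfac = (b1x*b2x+b1y*b2y+b1z*b2z)/(rb2*rb2);
    double qfac = (b3x*b2x+b3y*b2y+b3z*b2z)/(rb2*rb2);
    double tjx = (-pfac-1.0)*tix + qfac*tlx, tjy = (-pfac-1.0)*tiy + qfac*tly,
           tjz = (-pfac-1.0)*tiz + qfac*tlz;
    double tkx = pfac*tix + (-qfac-1.0)*tlx, tky = pfac*tiy + (-qfac-1.0)*tly,
           tkz = pfac*tiz + (-qfac-1.0)*tlz;
    FX[i] -= dv*tix; FY[i] -= dv*tiy; FZ[i] -= dv*tiz;
    FX[j] -= dv*tjx; FY[j] -= dv*tjy; FZ[j] -= dv*tjz;
    FX[k] -= dv*tkx; FY[k] -= dv*tky; FZ[k] -= dv*tkz;
    FX[l] -= dv*tlx; FY[l] -= dv*tly; FZ[l] -= dv*tlz;
  }
  // native contacts (Gaussian wells over an excluded-volume core)
  for (size_t r = 0; r < t.ci.size(); ++r) {
    int i = t.ci[r], j = t.cj[r];
    double dx = X[j]-X[i], dy = Y[j]-Y[i], dz = Z[j]-Z[i];
    double rr = std::sqrt(dx*dx + dy*dy + dz*dz);
    double s2 = t.sig[r] * t.sig[r];
    double g1 = std::exp(-(rr - t.r0a[r]) * (rr - t.r0a[r]) / (2.0 * s2));
    double dg1 = -((rr - t.r0a[r]) / s2) * g1;
    double P, dP;
    if (t.cdual[r]) {
      double g2 = std::exp(-(rr - t.r0b[r]) * (rr - t.r0b[r]) / (2.0 * s2));
      double dg2 = -((rr - t.r0b[r]) / s2) * g2;
      P = (1.0 - g1) * (1.0 - g2);
      dP = -dg1 * (1.0 - g2) - dg2 * (1.0 - g1);
    } else { P = 1.0 - g1; dP = -dg1; }
    double rex2 = t.rex[r]/rr; rex2 *= rex2;
    double a12 = rex2*rex2*rex2; a12 *= a12;
    double A = 1.0 + a12, dA = -12.0 * a12 / rr;
    ec += t.eps[r] * (A * P - 1.0);
    double s = t.eps[r] * (dA * P + A * dP) / rr;  // +dV/dr along unit(ij)
    FX[i] += s*dx; FY[i] += s*dy; FZ[i] += s*dz;
    FX[j] -= s*dx; FY[j] -= s*dy; FZ[j] -= s*dz;
  }
  // non-native excluded volume, shifted at rcut
  double shift = std::pow(t.rnn / t.rcut, 12);
  double rcut2 = t.rcut * t.rcut;
  for (size_t q = 0; q < nn.size(); ++q) {
    int i = nn[q].first, j = nn[q].second;
    double dx = X[j]-X[i], dy = Y[j]-Y[i], dz = Z[j]-Z[i];
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rcut2) continue;
    double q2 = t.rnn*t.rnn/r2;
    double a12 = q2*q2*q2; a12 *= a12;
    er += a12 - shift;
    double s = -12.0 * a12 / r2;
    FX[i] += s*dx; FY[i] += s*dy; FZ[i] += s*dz;
    FX[j] -= s*dx; FY[j] -= s*dy; FZ[j] -= s*dz;
  }
  e[0] = eb; e[1] = ea; e[2] = ed; e[3] = ec; e[4] = er;
}

static std::vector<std::pair<int,int>> build_nn(const Topo& t, const arma::mat& x,
                                                double reach) {
  std::vector<std::pair<int,int>> nn;
  double r2 = reach * reach;
  for (int i = 0; i < t.n; ++i)
    for (int j = i + 1; j < t.n; ++j) {
      if (t.excl.count(pk(i, j, t.n))) continue;
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      if (dx*dx + dy*dy + dz*dz < r2) nn.push_back({i, j});
    }
  return nn;
}

// [[Rcpp::export]]
List sbm_energy_cpp(List topo, NumericMatrix x_) {
  Topo t = parse_topo(topo);
  arma::mat x(x_.begin(), x_.nrow(), 3, false);
  arma::mat f(t.n, 3, arma::fill::zeros);
  std::vector<std::pair<int,int>> nn = build_nn(t, x, t.rcut);
  double e[5];
  eval_ef(t, x, f, nn, e);
  return List::create(_["bond"] = e[0], _["angle"] = e[1], _["dihedral"] = e[2],
                      _["contact"] = e[3], _["repulsion"] = e[4],
                      _["total"] = e[0]+e[1]+e[2]+e[3]+e[4],
                      _["forces"] = wrap(f));
}

// Best-fit (Kabsch) RMSD of rows sel of x against ref (nsel x 3).
static double kabsch_rmsd(const arma::mat& x, const arma::uvec& sel,
                          const arma::mat& ref) {
  arma::mat P = x.rows(sel);
  arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(ref, 0);
  arma::mat Pc = P.each_row() - cp, Qc = ref.each_row() - cq;
  arma::mat H = Pc.t() * Qc, U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3); D(2, 2) = d;
  arma::mat R = U * D * V.t();
  arma::mat E = Pc * R - Qc;
  return std::sqrt(arma::accu(E % E) / P.n_rows);
}

// Deterministic Gaussian stream: mt19937_64 + Box-Muller (independent of
// the platform's std::normal_distribution implementation).
struct GaussRNG {
  std::mt19937_64 eng;
  bool have; double spare;
  explicit GaussRNG(uint64_t seed) : eng(seed), have(false), spare(0) {}
  double unif() {  // (0,1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    if (have) { have = false; return spare; }
    double u = unif(), v = unif();
    double rad = std::sqrt(-2.0 * std::log(u)), ang = 2.0 * M_PI * v;
    spare = rad * std::sin(ang); have = true;
    return rad * std::cos(ang);
  }
};

// BAOAB Langevin integrator; all randomness from `seed`.
// [[Rcpp::export]]
List langevin_cpp(List topo, NumericMatrix x0_, double temperature, double dt,
                  double gamma, int sample_stride, double max_steps,
                  double stop_rmsd, IntegerVector stop_sel, NumericMatrix stop_ref_,
                  double energy_bound, int nlist_stride, double skin,
                  double seed) {
  Topo t = parse_topo(topo);
  GaussRNG rng(static_cast<uint64_t>(seed));
  arma::mat x(x0_.begin(), x0_.nrow(), 3);
  arma::mat v(t.n, 3), f(t.n, 3, arma::fill::zeros);
  if (temperature > 0) {
    double sv = std::sqrt(temperature);
    for (int i = 0; i < t.n; ++i) for (int k = 0; k < 3; ++k)
      v(i, k) = sv * rng();
  } else v.zeros();

  arma::uvec sel(stop_sel.size());
  for (int i = 0; i < stop_sel.size(); ++i) sel[i] = stop_sel[i] - 1;
  arma::mat stop_ref(stop_ref_.begin(), stop_ref_.nrow(), stop_ref_.ncol());
  bool has_stop = sel.n_elem > 0;

  double reach = t.rcut + skin;
  std::vector<std::pair<int,int>> nn = build_nn(t, x, reach);
  double e[5];
  eval_ef(t, x, f, nn, e);

  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (temperature > 0) ? std::sqrt((1.0 - c1 * c1) * temperature) : 0.0;

  std::vector<arma::mat> frames;
  std::vector<double> times, epot, ekin;
  std::string term = "max_steps";
  long steps_done = 0;

  auto record = [&](long step) {
    frames.push_back(x);
    times.push_back(step * dt);
    double ep = e[0]+e[1]+e[2]+e[3]+e[4];
    epot.push_back(ep);
    ekin.push_back(0.5 * arma::accu(v % v));
    return ep;
  };
  double ep0 = record(0);
  if (!std::isfinite(ep0) || std::fabs(ep0) > energy_bound) term = "diverged";
  else if (has_stop && kabsch_rmsd(x, sel, stop_ref) < stop_rmsd) term = "stop_rmsd";
  else {
    long nmax = (long)max_steps;
    for (long s = 1; s <= nmax; ++s) {
      v += 0.5 * dt * f;
      x += 0.5 * dt * v;
      if (gamma > 0 || temperature > 0) {
        for (int i = 0; i < t.n; ++i) for (int k = 0; k < 3; ++k)
          v(i, k) = c1 * v(i, k) + c2 * rng();
      }
      x += 0.5 * dt * v;
      if (s % nlist_stride == 0) nn = build_nn(t, x, reach);
      eval_ef(t, x, f, nn, e);
      v += 0.5 * dt * f;
      steps_done = s;
      if (s % sample_stride == 0) {
        double ep = record(s);
        if (!std::isfinite(ep) || std::fabs(ep) > energy_bound) { term = "diverged"; break; }
        if (has_stop && kabsch_rmsd(x, sel, stop_ref) < stop_rmsd) {
          term = "stop_rmsd"; break;
        }
        Rcpp::checkUserInterrupt();
      }
    }
  }
  arma::cube fc(t.n, 3, frames.size());
  for (size_t q = 0; q < frames.size(); ++q) fc.slice(q) = frames[q];
  return List::create(_["frames"] = wrap(fc), _["times"] = wrap(times),
                      _["epot"] = wrap(epot), _["ekin"] = wrap(ekin),
                      _["termination"] = term, _["steps"] = (double)steps_done);
}
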