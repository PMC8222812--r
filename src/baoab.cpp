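#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// BAOAB Langevin integrator over an elastic-network pair list with an
// optional double-well gate term.  Springs are given as atom index pairs
// (0-based) with unit separation vectors of the reference structure;
// kinetic excitations add alpha * direction to the velocities before the
// listed (0-based) steps.
// Units: x in Angstrom, v in Angstrom/ps, m in amu, energies in kcal/mol,
// forces in kcal/mol/A (E_CONV = 418.4 amu A^2/ps^2 per kcal/mol).

static const double E_CONV = 418.4;
static const double KB = 0.001987204259;

struct GateTerm {
  bool active = false;
  std::vector<int> idx;               // 0-based atom indices
  std::vector<double> ux, uy, tx, ty, z0;
  double c = 0, w2 = 1, h = 0, k_perp = 0;
};

// returns the gate energy and accumulates gate forces into f
static double gate_eval(const GateTerm& g, const std::vector<double>& x,
                        std::vector<double>& f) {
  if (!g.active) return 0.0;
  double e = 0.0;
  for (size_t a = 0; a < g.idx.size(); ++a) {
    const int ix = 3 * g.idx[a], iy = ix + 1, iz = ix + 2;
    const double s = x[ix] * g.ux[a] + x[iy] * g.uy[a];
    const double q = x[ix] * g.tx[a] + x[iy] * g.ty[a];
    const double dz = x[iz] - g.z0[a];
    const double sc = s - g.c;
    const double d2 = sc * sc - g.w2;
    e += g.h * d2 * d2 / (g.w2 * g.w2) + 0.5 * g.k_perp * (q * q + dz * dz);
    const double dUds = 4.0 * g.h * d2 * sc / (g.w2 * g.w2);
    const double dUdq = g.k_perp * q;
    f[ix] -= dUds * g.ux[a] + dUdq * g.tx[a];
    f[iy] -= dUds * g.uy[a] + dUdq * g.ty[a];
    f[iz] -= g.k_perp * dz;
  }
  return e;
}

// [[Rcpp::export(name = ".baoab_cpp")]]
List baoab_cpp(NumericVector x0, NumericVector v0, NumericVector m3,
               IntegerVector pair_i, IntegerVector pair_j,
               NumericVector ux_, NumericVector uy_, NumericVector uz_,
               double spring_k, NumericVector xref, int n_steps, double dt,
               double friction, double temperature, int record_stride,
               IntegerVector excite_steps, NumericVector direction,
               double alpha, List gate) {
  const int nd = x0.size();
  const int n_atoms = nd / 3;
  const int np = pair_i.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> dx(nd), f(nd), acc(nd);
  const double c1 = std::exp(-friction * dt);
  std::vector<double> c2(nd);
  for (int i = 0; i < nd; ++i)
    c2[i] = std::sqrt((1.0 - c1 * c1) * KB * temperature * E_CONV / m3[i]);
  const int* pi_ = INTEGER(pair_i);
  const int* pj_ = INTEGER(pair_j);
  const double* ux = REAL(ux_);
  const double* uy = REAL(uy_);
  const double* uz = REAL(uz_);

  GateTerm g;
  if (gate.size() > 0) {
    g.active = true;
    IntegerVector gi = gate["idx"];
    NumericVector gux = gate["ux"], guy = gate["uy"], gtx = gate["tx"],
                  gty = gate["ty"], gz0 = gate["z0"];
    g.idx.assign(gi.begin(), gi.end());
    g.ux.assign(gux.begin(), gux.end()); g.uy.assign(guy.begin(), guy.end());
    g.tx.assign(gtx.begin(), gtx.end()); g.ty.assign(gty.begin(), gty.end());
    g.z0.assign(gz0.begin(), gz0.end());
    g.c = as<double>(gate["c"]);
    const double w = as<double>(gate["w"]);
    g.w2 = w * w;
    g.h = as<double>(gate["h"]);
    g.k_perp = as<double>(gate["k_perp"]);
  }

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix frames(n_rec, nd);
  NumericVector temps(n_rec), energies(n_rec), steps(n_rec);

  std::set<int> exc(excite_steps.begin(), excite_steps.end());
  const bool do_excite = alpha != 0.0 && direction.size() == nd;

  // spring forces: f_i += k s u, f_j -= k s u with s = u.(dx_j - dx_i);
  // energy 0.5 k sum s^2
  auto eval_forces = [&]() -> double {
    for (int i = 0; i < nd; ++i) { dx[i] = x[i] - xref[i]; f[i] = 0.0; }
    double e = 0.0;
    for (int p = 0; p < np; ++p) {
      const int ia = 3 * pi_[p], ja = 3 * pj_[p];
      const double s = ux[p] * (dx[ja] - dx[ia]) +
                       uy[p] * (dx[ja + 1] - dx[ia + 1]) +
                       uz[p] * (dx[ja + 2] - dx[ia + 2]);
      e += s * s;
      const double ks = spring_k * s;
      f[ia] += ks * ux[p];     f[ja] -= ks * ux[p];
      f[ia + 1] += ks * uy[p]; f[ja + 1] -= ks * uy[p];
      f[ia + 2] += ks * uz[p]; f[ja + 2] -= ks * uz[p];
    }
    e *= 0.5 * spring_k;
    e += gate_eval(g, x, f);
    return e;
  };
  auto record = [&](int r, int step, double e) {
    double ke = 0.0;
    for (int i = 0; i < nd; ++i) {
      frames(r, i) = x[i];
      ke += m3[i] * v[i] * v[i];
    }
    ke *= 0.5 / E_CONV;
    temps[r] = 2.0 * ke / (3.0 * n_atoms * KB);
    energies[r] = e;
    steps[r] = step;
  };

  GetRNGstate();
  double e = eval_forces();
  bool finite = R_finite(e);
  for (int i = 0; i < nd && finite; ++i) finite = R_finite(f[i]);
  if (!finite) {
    PutRNGstate();
    stop("non-finite forces/energy at step 0");
  }
  for (int i = 0; i < nd; ++i) acc[i] = f[i] * E_CONV / m3[i];
  if (do_excite && exc.count(0))
    for (int i = 0; i < nd; ++i) v[i] += alpha * direction[i];
  int r = 0;
  record(r++, 0, e);
  int bad_step = -1;
  for (int s = 1; s <= n_steps; ++s) {
    if (do_excite && exc.count(s))
      for (int i = 0; i < nd; ++i) v[i] += alpha * direction[i];
    for (int i = 0; i < nd; ++i) {
      v[i] += 0.5 * dt * acc[i];
      x[i] += 0.5 * dt * v[i];
      v[i] = c1 * v[i] + c2[i] * norm_rand();
      x[i] += 0.5 * dt * v[i];
    }
    e = eval_forces();
    finite = R_finite(e);
    for (int i = 0; i < nd && finite; ++i) finite = R_finite(f[i]);
    if (!finite) { bad_step = s; break; }
    for (int i = 0; i < nd; ++i) {
      acc[i] = f[i] * E_CONV / m3[i];
      v[i] += 0.5 * dt * acc[i];
    }
    if (s % record_stride == 0) record(r++, s, e);
  }
  PutRNGstate();
  if (bad_step >= 0)
    stop("non-finite forces/energy at step %d", bad_step);

  NumericVector vfin(v.begin(), v.end());
  return List::create(_["frames"] = frames, _["temps"] = temps,
                      _["energies"] = energies, _["steps"] = steps,
                      _["v_final"] = vfin);
}
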