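// Core numerics for the multicompartment RGC model: channel gating rates,
// gating-state advancement, calcium shell dynamics, and the implicit
// cable-equation stepper on the compartment tree (Hines-ordered elimination,
// one O(N) sweep per time step).
//
// Units throughout: mV, ms, nA, uS, nF, S/cm2 (densities), cm2 (areas),
// M (calcium), mA/cm2 (membrane current densities).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gate indices: 0 m, 1 h, 2 c, 3 n, 4 a, 5 hA, 6 l, 7 mT, 8 hT, 9 d, 10 p
static const int N_GATES = 11;

// k*x / (1 - exp(-s*x)) with the removable singularity at x = 0 evaluated by
// a second-order series when |x| is tiny (limit k/s).
static inline double lin_exp(double x, double k, double s) {
  if (std::fabs(x) < 1e-6) return (k / s) * (1.0 + 0.5 * s * x);
  return k * x / (-std::expm1(-s * x));
}

// Voltage-dependent transition rates (1/ms) for each gate.
static inline void gate_ab(int g, double v, double &a, double &b) {
  switch (g) {
  case 0: // m (Na activation); alpha singular at v = -30
    a = lin_exp(v + 30.0, 0.6, 0.1);
    b = 20.0 * std::exp(-(v + 55.0) / 18.0);
    break;
  case 1: // h (Na inactivation)
    a = 0.4 * std::exp(-(v + 50.0) / 20.0);
    b = 6.0 / (1.0 + std::exp(-0.1 * (v + 20.0)));
    break;
  case 2: // c (HVA Ca activation); alpha singular at v = -13
    a = lin_exp(v + 13.0, 0.3, 0.1);
    b = 10.0 * std::exp(-(v + 38.0) / 18.0);
    break;
  case 3: // n (delayed rectifier); alpha singular at v = -40
    a = lin_exp(v + 40.0, 0.02, 0.1);
    b = 0.4 * std::exp(-(v + 50.0) / 80.0);
    break;
  case 4: // a (K-A activation); alpha singular at v = -90
    a = lin_exp(v + 90.0, 0.006, 0.1);
    b = 0.1 * std::exp(-(v + 30.0) / 10.0);
    break;
  case 5: // hA (K-A inactivation)
    a = 0.04 * std::exp(-(v + 70.0) / 20.0);
    b = 0.6 / (1.0 + std::exp(-0.1 * (v + 40.0)));
    break;
  case 6: // l (h-current)
    a = std::exp(0.08316 * (v + 75.0));
    b = std::exp(0.033264 * (v + 75.0));
    break;
  case 7: { // mT (T-current activation)
    double den = 1.7 + std::exp(-(v + 28.8) / 13.5);
    a = 1.0 / den;
    b = (1.0 + std::exp(-(v + 63.0) / 7.8)) / den;
    break;
  }
  case 8: { // hT (T-current inactivation, open <-> closed 1)
    a = std::exp(-(v + 160.3) / 17.8);
    double s = std::sqrt(0.25 + std::exp((v + 83.5) / 6.3));
    b = a * (s - 0.5);
    break;
  }
  case 9: { // d (T-current second closed state)
    double s = std::sqrt(0.25 + std::exp((v + 83.5) / 6.3));
    a = (1.0 + std::exp((v + 37.4) / 30.0)) / (240.0 * (0.5 + s));
    b = a * s;
    break;
  }
  case 10: { // p (NaP), piecewise in V at -40 mV
    double pinf = 1.0 / (1.0 + std::exp(-(v + 48.0) / 10.0));
    double tau = (v < -40.0) ? 0.025 + 0.14 * std::exp((v + 40.0) / 10.0)
                             : 0.02 + 0.145 * std::exp(-(v + 40.0) / 10.0);
    a = pinf / tau;
    b = (1.0 - pinf) / tau;
    break;
  }
  default:
    stop("unknown gate index");
  }
}

// Equilibrium of the coupled (hT, d) system at fixed voltage: solves
// a_h*(1-h-d) = b_h*h, b_d*(1-h-d) = a_d*d.
static inline void ht_d_equilibrium(double v, double &h, double &d) {
  double ah, bh, ad, bd;
  gate_ab(8, v, ah, bh);
  gate_ab(9, v, ad, bd);
  double u = 1.0 / (1.0 + ah / bh + bd / ad);
  h = ah / bh * u;
  d = bd / ad * u;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// One gating step at frozen voltage: exact exponential relaxation for the
// first-order gates, one backward-Euler step for the linear (hT, d) pair.
static inline void step_gates(double *g, double v, double dt) {
  for (int k = 0; k < N_GATES; ++k) {
    if (k == 8 || k == 9) continue;
    double a, b;
    gate_ab(k, v, a, b);
    double xinf = a / (a + b);
    g[k] = clamp01(xinf + (g[k] - xinf) * std::exp(-dt * (a + b)));
  }
  double ah, bh, ad, bd;
  gate_ab(8, v, ah, bh);
  gate_ab(9, v, ad, bd);
  // (1 + dt*(ah+bh)) h' + dt*ah d' = h + dt*ah
  // dt*bd h' + (1 + dt*(bd+ad)) d' = d + dt*bd
  double a11 = 1.0 + dt * (ah + bh), a12 = dt * ah;
  double a21 = dt * bd, a22 = 1.0 + dt * (bd + ad);
  double r1 = g[8] + dt * ah, r2 = g[9] + dt * bd;
  double det = a11 * a22 - a12 * a21;
  double h = (r1 * a22 - a12 * r2) / det;
  double d = (a11 * r2 - r1 * a21) / det;
  g[8] = clamp01(h);
  g[9] = clamp01(d);
  if (g[8] + g[9] > 1.0) { // renormalise occupancies if clipping broke the sum
    double s = g[8] + g[9];
    g[8] /= s;
    g[9] /= s;
  }
}

// [[Rcpp::export]]
NumericMatrix gate_rates_cpp(int gate, NumericVector v) {
  int n = v.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double a, b;
    gate_ab(gate, v[i], a, b);
    out(i, 0) = a;
    out(i, 1) = b;
  }
  colnames(out) = CharacterVector::create("alpha", "beta");
  return out;
}

// [[Rcpp::export]]
NumericMatrix steady_gates_cpp(NumericVector v) {
  int n = v.size();
  NumericMatrix out(n, N_GATES);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < N_GATES; ++k) {
      if (k == 8 || k == 9) continue;
      double a, b;
      gate_ab(k, v[i], a, b);
      out(i, k) = a / (a + b);
    }
    double h, d;
    ht_d_equilibrium(v[i], h, d);
    out(i, 8) = h;
    out(i, 9) = d;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix advance_gates_cpp(NumericMatrix state, NumericVector v, double dt) {
  int n = state.nrow();
  if (v.size() != n) stop("state/voltage length mismatch");
  NumericMatrix out = clone(state);
  std::vector<double> g(N_GATES);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < N_GATES; ++k) g[k] = out(i, k);
    step_gates(g.data(), v[i], dt);
    for (int k = 0; k < N_GATES; ++k) out(i, k) = g[k];
  }
  return out;
}

// Full current-clamp integration on the compartment tree.
//
// parent: 0-based parent index, -1 for the root; compartments must be ordered
//   with parent before child. g_axial: coupling to parent in uS. dens: n x 9
//   channel densities (S/cm2), columns na, ca, k, ka, kca_max, l, h, nap, t.
// consts: named vector with cm, v_na, v_k, v_l, v_h, v_t, ca_e, ca_diss,
//   ca_res, tau_ca, rt2f_mv, ca_drive (M per ms per mA/cm2).
// stim: per-step injected current (nA) at stim_comp. The settle phase runs
//   settle_steps with no stimulus before recording starts.
// [[Rcpp::export]]
List simulate_core(IntegerVector parent, NumericVector area_cm2,
                   NumericVector g_axial, NumericMatrix dens,
                   NumericVector consts, double dt, int n_steps,
                   int settle_steps, NumericVector stim, int stim_comp,
                   IntegerVector record_idx, bool record_currents,
                   double v_init, bool crank_nicolson) {
  int n = parent.size();
  if (area_cm2.size() != n || g_axial.size() != n || dens.nrow() != n)
    stop("inconsistent cell arrays");
  if (stim.size() != n_steps) stop("stimulus length must equal n_steps");
  for (int i = 1; i < n; ++i)
    if (parent[i] < 0 || parent[i] >= i) stop("compartments not in tree order");

  double cm = consts["cm"], v_na = consts["v_na"], v_k = consts["v_k"],
         v_l = consts["v_l"], v_h = consts["v_h"], v_t = consts["v_t"],
         ca_e = consts["ca_e"], ca_diss = consts["ca_diss"],
         ca_res = consts["ca_res"], tau_ca = consts["tau_ca"],
         rt2f = consts["rt2f_mv"], ca_drive = consts["ca_drive"];

  std::vector<double> v(n, v_init), ca(n, ca_res), vca(n);
  std::vector<std::vector<double> > gates(n, std::vector<double>(N_GATES));
  {
    NumericMatrix g0 = steady_gates_cpp(NumericVector::create(v_init));
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < N_GATES; ++k) gates[i][k] = g0(0, k);
  }
  for (int i = 0; i < n; ++i) vca[i] = rt2f * std::log(ca_e / ca[i]);

  // per-compartment capacitance (nF) and membrane conductance scale (uS)
  std::vector<double> cap_nf(n), area_us(n);
  for (int i = 0; i < n; ++i) {
    cap_nf[i] = cm * area_cm2[i] * 1e3;
    area_us[i] = area_cm2[i] * 1e6;
  }

  // Voltage-indexed lookup tables for the gating updates (0.05 mV grid,
  // linear interpolation): per first-order gate the steady state and the
  // per-step relaxation factor exp(-dt*(a+b)); per (hT, d) rate the raw rates.
  const double v_lo = -150.0, v_hi = 60.0, dv = 0.05;
  const int nbins = (int)((v_hi - v_lo) / dv) + 1;
  const int FO[9] = {0, 1, 2, 3, 4, 5, 6, 7, 10};
  const int NSLOT = 22;
  std::vector<double> tab((size_t)nbins * NSLOT);
  for (int b = 0; b < nbins; ++b) {
    double vb = v_lo + b * dv;
    double *row = &tab[(size_t)b * NSLOT];
    for (int gi = 0; gi < 9; ++gi) {
      double a, bb;
      gate_ab(FO[gi], vb, a, bb);
      row[2 * gi] = a / (a + bb);
      row[2 * gi + 1] = std::exp(-dt * (a + bb));
    }
    gate_ab(8, vb, row[18], row[19]);
    gate_ab(9, vb, row[20], row[21]);
  }

  int nrec = record_idx.size();
  NumericMatrix v_out(n_steps + 1, nrec);
  // per-channel current densities (mA/cm2) at recorded sites
  const int N_CUR = 9;
  List cur_out(0);
  std::vector<NumericMatrix> cur_mats;
  if (record_currents) {
    for (int c = 0; c < N_CUR; ++c)
      cur_mats.push_back(NumericMatrix(n_steps + 1, nrec));
  }

  std::vector<double> D(n), rhs(n), Gtot(n), GE(n), icur(N_CUR);
  double vdt = crank_nicolson ? dt * 0.5 : dt;
  int total_steps = settle_steps + n_steps;

  for (int step = 0; step < total_steps; ++step) {
    bool recording = step >= settle_steps;
    int rstep = step - settle_steps;
    if (recording && rstep == 0) {
      for (int j = 0; j < nrec; ++j) v_out(0, j) = v[record_idx[j]];
    }
    // 1. gates, 2. calcium (exact linear update at frozen I_Ca), 3. voltage
    for (int i = 0; i < n; ++i) {
      {
        double pos = (v[i] - v_lo) / dv;
        if (pos < 0) pos = 0;
        if (pos > nbins - 1.001) pos = nbins - 1.001;
        int b = (int)pos;
        double w = pos - b;
        const double *r0 = &tab[(size_t)b * NSLOT];
        const double *r1 = r0 + NSLOT;
        double *g = gates[i].data();
        for (int gi = 0; gi < 9; ++gi) {
          double xinf = r0[2 * gi] + w * (r1[2 * gi] - r0[2 * gi]);
          double ed = r0[2 * gi + 1] + w * (r1[2 * gi + 1] - r0[2 * gi + 1]);
          int k = FO[gi];
          g[k] = xinf + (g[k] - xinf) * ed;
        }
        double ah = r0[18] + w * (r1[18] - r0[18]);
        double bh = r0[19] + w * (r1[19] - r0[19]);
        double ad = r0[20] + w * (r1[20] - r0[20]);
        double bd = r0[21] + w * (r1[21] - r0[21]);
        double a11 = 1.0 + dt * (ah + bh), a12 = dt * ah;
        double a21 = dt * bd, a22 = 1.0 + dt * (bd + ad);
        double r1v = g[8] + dt * ah, r2v = g[9] + dt * bd;
        double det = a11 * a22 - a12 * a21;
        double hh = (r1v * a22 - a12 * r2v) / det;
        double dd2 = (a11 * r2v - r1v * a21) / det;
        g[8] = clamp01(hh);
        g[9] = clamp01(dd2);
        if (g[8] + g[9] > 1.0) {
          double s = g[8] + g[9];
          g[8] /= s;
          g[9] /= s;
        }
      }
      double c3 = gates[i][2] * gates[i][2] * gates[i][2];
      double i_ca = dens(i, 1) * c3 * (v[i] - vca[i]); // mA/cm2
      double ca_inf = ca_res - ca_drive * i_ca * tau_ca;
      ca[i] = ca_inf + (ca[i] - ca_inf) * std::exp(-dt / tau_ca);
      if (ca[i] < 1e-12) ca[i] = 1e-12;
      vca[i] = rt2f * std::log(ca_e / ca[i]);

      double m3h = gates[i][0] * gates[i][0] * gates[i][0] * gates[i][1];
      double n4 = gates[i][3] * gates[i][3] * gates[i][3] * gates[i][3];
      double a3ha = gates[i][4] * gates[i][4] * gates[i][4] * gates[i][5];
      double mt3ht = gates[i][7] * gates[i][7] * gates[i][7] * gates[i][8];
      double y = (ca[i] / ca_diss) * (ca[i] / ca_diss);
      double gkca = dens(i, 4) * y / (1.0 + y);

      double g_na = dens(i, 0) * m3h, g_ca = dens(i, 1) * c3,
             g_k = dens(i, 2) * n4, g_ka = dens(i, 3) * a3ha,
             g_l = dens(i, 5), g_h = dens(i, 6) * gates[i][6],
             g_nap = dens(i, 7) * gates[i][10], g_t = dens(i, 8) * mt3ht;
      Gtot[i] = g_na + g_ca + g_k + g_ka + gkca + g_l + g_h + g_nap + g_t;
      GE[i] = g_na * v_na + g_ca * vca[i] + (g_k + g_ka + gkca) * v_k +
              g_l * v_l + g_h * v_h + g_nap * v_na + g_t * v_t;
      if (record_currents && recording) {
        for (int j = 0; j < nrec; ++j) {
          if (record_idx[j] == i) {
            cur_mats[0](rstep + 1, j) = g_na * (v[i] - v_na);
            cur_mats[1](rstep + 1, j) = g_ca * (v[i] - vca[i]);
            cur_mats[2](rstep + 1, j) = g_k * (v[i] - v_k);
            cur_mats[3](rstep + 1, j) = g_ka * (v[i] - v_k);
            cur_mats[4](rstep + 1, j) = gkca * (v[i] - v_k);
            cur_mats[5](rstep + 1, j) = g_l * (v[i] - v_l);
            cur_mats[6](rstep + 1, j) = g_h * (v[i] - v_h);
            cur_mats[7](rstep + 1, j) = g_nap * (v[i] - v_na);
            cur_mats[8](rstep + 1, j) = g_t * (v[i] - v_t);
          }
        }
      }
    }
    // assemble the implicit (backward Euler over vdt) tree system
    for (int i = 0; i < n; ++i) {
      double cdt = cap_nf[i] / vdt;
      D[i] = cdt + area_us[i] * Gtot[i];
      rhs[i] = cdt * v[i] + area_us[i] * GE[i];
      if (i > 0) D[i] += g_axial[i];
    }
    for (int i = 1; i < n; ++i) D[parent[i]] += g_axial[i];
    if (recording) rhs[stim_comp] += stim[rstep];
    // Hines elimination: children (higher index) folded into parents
    for (int i = n - 1; i >= 1; --i) {
      double f = g_axial[i] / D[i];
      D[parent[i]] -= g_axial[i] * f;
      rhs[parent[i]] += rhs[i] * f;
    }
    double v_new0 = rhs[0] / D[0];
    if (!std::isfinite(v_new0))
      stop("voltage became non-finite at t = %f ms", (step - settle_steps) * dt);
    if (crank_nicolson) {
      std::vector<double> vh(n);
      vh[0] = v_new0;
      for (int i = 1; i < n; ++i)
        vh[i] = (rhs[i] + g_axial[i] * vh[parent[i]]) / D[i];
      for (int i = 0; i < n; ++i) v[i] = 2.0 * vh[i] - v[i];
    } else {
      v[0] = v_new0;
      for (int i = 1; i < n; ++i)
        v[i] = (rhs[i] + g_axial[i] * v[parent[i]]) / D[i];
    }
    if (recording) {
      for (int j = 0; j < nrec; ++j) v_out(rstep + 1, j) = v[record_idx[j]];
    }
  }

  List out = List::create(Named("v") = v_out);
  if (record_currents) {
    List cl(N_CUR);
    CharacterVector nm = CharacterVector::create("na", "ca", "k", "ka", "kca",
                                                 "l", "h", "nap", "t");
    for (int c = 0; c < N_CUR; ++c) cl[c] = cur_mats[c];
    cl.attr("names") = nm;
    out["currents"] = cl;
  }
  return out;
}
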