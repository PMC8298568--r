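// Closed-loop lumped-parameter network of Fontan circulation.
//
// Nine stressed-volume states: single ventricle (time-varying elastance),
// atrium, aorta/systemic arteries, upper-body bed, SVC, lower-body bed,
// IVC/Fontan inlet (graft compliance lumped here), pulmonary arteries,
// pulmonary veins.  Connections are resistive; the Fontan conduit carries a
// nonlinear two-term loss dP = R*Q + K*Q|Q| inverted in closed form; valves
// are smoothed diodes.  Thoracic compartments see a zero-mean respiratory
// pressure offset.  Working with stressed volumes makes total stressed
// volume conserved exactly by construction.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parameter vector layout (keep in step with lpn_par_vector() on the R side)
enum Par {
  P_HR, P_TRESP, P_RESPAMP, P_EMAX, P_EMIN, P_T1FRAC, P_T2FRAC,
  P_RAV, P_RVAO, P_EAT, P_CAO, P_RUBA, P_CUB, P_RUBV, P_CSVC, P_RSVC,
  P_RLBA, P_CLB, P_RLBV, P_CIVC, P_RGR, P_KGR, P_RLPA, P_RRPA, P_CPA,
  P_RPV, P_CPUL, P_VEPS, P_LINVALVE, NPAR
};

static const int NSTATE = 9;  // v, at, ao, ub, svc, lb, ivc, pa, pul

// normalized elastance activation, C1, peak 1 at s = t1
static inline double activation(double s, double t1, double t2) {
  if (s < t1) return 0.5 * (1.0 - std::cos(M_PI * s / t1));
  if (s < t2) return 0.5 * (1.0 + std::cos(M_PI * (s - t1) / (t2 - t1)));
  return 0.0;
}

// positive modulus without libm fmod
static inline double phase_of(double t, double T) {
  double s = t / T;
  return s - std::floor(s);
}

static inline double elastance_at(double t, const double* p) {
  double T = 60.0 / p[P_HR];
  double s = phase_of(t, T);
  double a = activation(s, p[P_T1FRAC], p[P_T2FRAC]);
  return p[P_EMIN] + (p[P_EMAX] - p[P_EMIN]) * a;
}

static inline double resp_pressure_at(double t, const double* p) {
  if (p[P_RESPAMP] == 0.0) return 0.0;
  return -p[P_RESPAMP] * std::sin(2.0 * M_PI * t / p[P_TRESP]);
}

// smoothed diode flow through a valve of resistance r
static inline double valve_flow(double dp, double r, double eps, bool linear) {
  if (linear) return dp / r;
  return 0.5 * (dp + std::sqrt(dp * dp + eps * eps)) / r;
}

// invert dp = R*q + K*q*|q|
static inline double graft_flow(double dp, double R, double K) {
  if (K <= 1e-14) return dp / R;
  double s = dp >= 0 ? 1.0 : -1.0;
  double x = std::fabs(dp);
  return s * (-R + std::sqrt(R * R + 4.0 * K * x)) / (2.0 * K);
}

struct NetEval {
  double pr[NSTATE];   // node pressures
  double q[11];        // q_av q_vao q_ua q_uv q_svc q_la q_lv q_gr q_lpa q_rpa q_pv
  double pth;
};

static void eval_network(double t, const double* v, const double* p,
                         NetEval& e, double* dv) {
  double pth = resp_pressure_at(t, p);
  e.pth = pth;
  double Ev = elastance_at(t, p);
  double P_v   = Ev * v[0] + pth;
  double P_at  = p[P_EAT] * v[1] + pth;
  double P_ao  = v[2] / p[P_CAO];
  double P_ub  = v[3] / p[P_CUB];
  double P_svc = v[4] / p[P_CSVC];
  double P_lb  = v[5] / p[P_CLB];
  double P_ivc = v[6] / p[P_CIVC];
  double P_pa  = v[7] / p[P_CPA] + pth;
  double P_pul = v[8] / p[P_CPUL] + pth;
  e.pr[0] = P_v;  e.pr[1] = P_at;  e.pr[2] = P_ao;  e.pr[3] = P_ub;
  e.pr[4] = P_svc; e.pr[5] = P_lb; e.pr[6] = P_ivc; e.pr[7] = P_pa;
  e.pr[8] = P_pul;

  bool lin = p[P_LINVALVE] != 0.0;
  double eps = p[P_VEPS];
  double q_av  = valve_flow(P_at - P_v, p[P_RAV], eps, lin);
  double q_vao = valve_flow(P_v - P_ao, p[P_RVAO], eps, lin);
  double q_ua  = (P_ao - P_ub) / p[P_RUBA];
  double q_uv  = (P_ub - P_svc) / p[P_RUBV];
  double q_svc = (P_svc - P_pa) / p[P_RSVC];
  double q_la  = (P_ao - P_lb) / p[P_RLBA];
  double q_lv  = (P_lb - P_ivc) / p[P_RLBV];
  double q_gr  = graft_flow(P_ivc - P_pa, p[P_RGR], p[P_KGR]);
  double q_lpa = (P_pa - P_pul) / p[P_RLPA];
  double q_rpa = (P_pa - P_pul) / p[P_RRPA];
  double q_pv  = (P_pul - P_at) / p[P_RPV];
  e.q[0] = q_av;  e.q[1] = q_vao; e.q[2] = q_ua;  e.q[3] = q_uv;
  e.q[4] = q_svc; e.q[5] = q_la;  e.q[6] = q_lv;  e.q[7] = q_gr;
  e.q[8] = q_lpa; e.q[9] = q_rpa; e.q[10] = q_pv;

  dv[0] = q_av - q_vao;          // ventricle
  dv[1] = q_pv - q_av;           // atrium
  dv[2] = q_vao - q_ua - q_la;   // aorta
  dv[3] = q_ua - q_uv;           // upper body
  dv[4] = q_uv - q_svc;          // SVC
  dv[5] = q_la - q_lv;           // lower body
  dv[6] = q_lv - q_gr;           // IVC / Fontan inlet
  dv[7] = q_svc + q_gr - q_lpa - q_rpa;  // pulmonary arteries
  dv[8] = q_lpa + q_rpa - q_pv;  // pulmonary veins
}

// [[Rcpp::export]]
NumericVector lpn_derivs_cpp(double t, NumericVector state, NumericVector par) {
  if (state.size() != NSTATE || par.size() != NPAR)
    stop("bad state or parameter vector length");
  NetEval e; double dv[NSTATE];
  eval_network(t, state.begin(), par.begin(), e, dv);
  NumericVector out(NSTATE);
  for (int i = 0; i < NSTATE; ++i) out[i] = dv[i];
  return out;
}

// [[Rcpp::export]]
List lpn_eval_cpp(double t, NumericVector state, NumericVector par) {
  NetEval e; double dv[NSTATE];
  eval_network(t, state.begin(), par.begin(), e, dv);
  NumericVector pr(NSTATE), q(11), d(NSTATE);
  for (int i = 0; i < NSTATE; ++i) { pr[i] = e.pr[i]; d[i] = dv[i]; }
  for (int i = 0; i < 11; ++i) q[i] = e.q[i];
  return List::create(_["pressures"] = pr, _["flows"] = q,
                      _["derivs"] = d, _["pth"] = e.pth);
}

// [[Rcpp::export]]
double elastance_cpp(double t, NumericVector par) {
  return elastance_at(t, par.begin());
}

static inline void rk4_step(double t, double dt, double* v, const double* p) {
  NetEval e;
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  eval_network(t, v, p, e, k1);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = v[i] + 0.5 * dt * k1[i];
  eval_network(t + 0.5 * dt, tmp, p, e, k2);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = v[i] + 0.5 * dt * k2[i];
  eval_network(t + 0.5 * dt, tmp, p, e, k3);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = v[i] + dt * k3[i];
  eval_network(t + dt, tmp, p, e, k4);
  for (int i = 0; i < NSTATE; ++i)
    v[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Integrate respiratory cycle by respiratory cycle until the cycle means of
// all node pressures settle, then record one further cycle as the trace.
// [[Rcpp::export]]
List lpn_integrate_cpp(NumericVector par, NumericVector state0,
                       double dt = 2e-4, double out_dt = 1e-3,
                       int max_cycles = 80, double tol = 1e-3,
                       int min_cycles = 4) {
  if (par.size() != NPAR) stop("bad parameter vector length");
  if (state0.size() != NSTATE) stop("bad initial state length");
  const double* p = par.begin();
  double T_resp = p[P_TRESP];
  int nstep = (int)std::ceil(T_resp / dt);
  double h = T_resp / nstep;

  double v[NSTATE];
  for (int i = 0; i < NSTATE; ++i) v[i] = state0[i];

  NumericMatrix mean_hist(max_cycles, NSTATE);
  NumericVector resid_hist(max_cycles);
  double prev_mean[NSTATE];
  bool converged = false;
  int cyc = 0;
  double t = 0.0;
  NetEval e; double dv[NSTATE];

  for (cyc = 0; cyc < max_cycles; ++cyc) {
    double sum[NSTATE] = {0};
    for (int s = 0; s < nstep; ++s) {
      eval_network(t, v, p, e, dv);
      for (int i = 0; i < NSTATE; ++i) {
        if (!std::isfinite(v[i])) stop("integration failure: non-finite state");
        sum[i] += e.pr[i];
      }
      rk4_step(t, h, v, p);
      t += h;
    }
    double resid = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double m = sum[i] / nstep;
      mean_hist(cyc, i) = m;
      if (cyc > 0) {
        double r = std::fabs(m - prev_mean[i]) / (std::fabs(m) + 0.1);
        if (r > resid) resid = r;
      }
      prev_mean[i] = m;
    }
    resid_hist[cyc] = cyc > 0 ? resid : NA_REAL;
    if (cyc + 1 >= min_cycles && cyc > 0 && resid <= tol) {
      converged = true; ++cyc; break;
    }
  }

  // record one more respiratory cycle
  int rec_every = std::max(1, (int)std::lround(out_dt / h));
  int nrec = nstep / rec_every + 1 + (nstep % rec_every ? 1 : 0);
  NumericMatrix trace(nrec, 1 + NSTATE + NSTATE + 11 + 1);
  int row = 0;
  double t0 = t;
  for (int s = 0; s <= nstep; ++s) {
    if (s % rec_every == 0 || s == nstep) {
      if (row < nrec) {
        eval_network(t, v, p, e, dv);
        trace(row, 0) = t - t0;
        for (int i = 0; i < NSTATE; ++i) trace(row, 1 + i) = v[i];
        for (int i = 0; i < NSTATE; ++i) trace(row, 1 + NSTATE + i) = e.pr[i];
        for (int i = 0; i < 11; ++i) trace(row, 1 + 2 * NSTATE + i) = e.q[i];
        trace(row, 1 + 2 * NSTATE + 11) = e.pth;
        ++row;
      }
    }
    if (s < nstep) { rk4_step(t, h, v, p); t += h; }
  }

  NumericVector final_state(NSTATE);
  for (int i = 0; i < NSTATE; ++i) final_state[i] = v[i];

  return List::create(
    _["trace"] = trace, _["converged"] = converged, _["n_cycles"] = cyc,
    _["residual"] = resid_hist[std::min(cyc - 1, max_cycles - 1)],
    _["mean_history"] = mean_hist, _["residual_history"] = resid_hist,
    _["final_state"] = final_state, _["dt"] = h);
}
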