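#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// State layout (14 components):
// 0 S_OFF, 1 S_ON, 2 S_IN1, 3 S_IN2, 4 S_PKA, 5 S_AD, 6 S_ADON,
// 7 DAG, 8 cAMP, 9 R, 10 C, 11 RC, 12 AD, 13 D
#define NSTATE 14

struct Pars {
  double kA1, kA2, kA3, kA4, kA5;
  double kDAGp, kDAGd;
  double kB1, kB2, kB2a, kB2b;
  double kC1, kC2, kC2a, kC2b;
  double kD1, kD1a, kD1b, kD2a, kD2b, kD3, kD3a, kD3b;
  double kS1, kS1a, kS1b, kS2, kS3, kS3a, kS3b, kS4;
  double Vm, K5HT, cAMP_basal, Kfpka, Kbpka, kcAMPd;
  double delayD, intPKA, intPKC;
};

static double getp(const NumericVector& p, const char* name) {
  CharacterVector nm = p.names();
  for (int i = 0; i < p.size(); ++i)
    if (std::strcmp(nm[i], name) == 0) return p[i];
  stop("parameter '%s' missing", name);
  return NA_REAL; // not reached
}

static Pars unpack(const NumericVector& p) {
  Pars P;
  P.kA1 = getp(p, "kA1"); P.kA2 = getp(p, "kA2"); P.kA3 = getp(p, "kA3");
  P.kA4 = getp(p, "kA4"); P.kA5 = getp(p, "kA5");
  P.kDAGp = getp(p, "kDAGp"); P.kDAGd = getp(p, "kDAGd");
  P.kB1 = getp(p, "kB1"); P.kB2 = getp(p, "kB2");
  P.kB2a = getp(p, "kB2a"); P.kB2b = getp(p, "kB2b");
  P.kC1 = getp(p, "kC1"); P.kC2 = getp(p, "kC2");
  P.kC2a = getp(p, "kC2a"); P.kC2b = getp(p, "kC2b");
  P.kD1 = getp(p, "kD1"); P.kD1a = getp(p, "kD1a"); P.kD1b = getp(p, "kD1b");
  P.kD2a = getp(p, "kD2a"); P.kD2b = getp(p, "kD2b");
  P.kD3 = getp(p, "kD3"); P.kD3a = getp(p, "kD3a"); P.kD3b = getp(p, "kD3b");
  P.kS1 = getp(p, "kS1"); P.kS1a = getp(p, "kS1a"); P.kS1b = getp(p, "kS1b");
  P.kS2 = getp(p, "kS2");
  P.kS3 = getp(p, "kS3"); P.kS3a = getp(p, "kS3a"); P.kS3b = getp(p, "kS3b");
  P.kS4 = getp(p, "kS4");
  P.Vm = getp(p, "Vm"); P.K5HT = getp(p, "K5HT");
  P.cAMP_basal = getp(p, "cAMP_basal");
  P.Kfpka = getp(p, "Kfpka"); P.Kbpka = getp(p, "Kbpka");
  P.kcAMPd = getp(p, "kcAMPd");
  P.delayD = getp(p, "delayD"); P.intPKA = getp(p, "intPKA");
  P.intPKC = getp(p, "intPKC");
  return P;
}

// Hill functions; the argument is clamped at 0 so that transient solver
// undershoot (|x| ~ 1e-12) cannot produce NaN through fractional exponents.
static inline double hill_act(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return xn / (Kn + xn);
}
static inline double hill_inh(double x, double K, double n) {
  if (x <= 0.0) return 1.0;
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return Kn / (Kn + xn);
}

// Right-hand side of the full system. fiveHT is the serotonin concentration;
// `aniso` zeroes AD/D synthesis; `kt` clamps PKA activity (free catalytic
// subunit C) to zero wherever it drives receptor/synthesis terms, while the
// internal cAMP/R/C/RC dynamics keep evolving. `ipkc` and `ipka` are the
// windowed history integrals supplied by the integrator. dS_OFF/dt is minus
// the sum of the other six receptor derivatives, so receptor conservation
// holds exactly by construction.
static void deriv(const double* y, double fiveHT, bool aniso, bool kt,
                  double ipkc, double ipka, const Pars& P, double* dy) {
  double C_eff = kt ? 0.0 : y[10];
  double AD = y[12] > 0.0 ? y[12] : 0.0;
  double D  = y[13] > 0.0 ? y[13] : 0.0;

  double f_act    = P.kA1 * fiveHT * y[0];          // S_OFF -> S_ON
  double f_inact  = P.kA2 * y[1];                   // S_ON -> S_IN1
  double f_rec1   = P.kA3 * y[2];                   // S_IN1 -> S_OFF
  double f_sort   = P.kA4 * y[2];                   // S_IN1 -> S_IN2
  double f_rec2   = P.kA5 * y[3];                   // S_IN2 -> S_OFF
  double f_pka_in = (P.kB1 * C_eff + P.kD1 * D) *
                    hill_inh(AD, P.kD1a, P.kD1b) * y[0]; // S_OFF -> S_PKA
  double f_pka_out = P.kB2 * hill_inh(C_eff, P.kB2a, P.kB2b) *
                     hill_inh(D, P.kD2a, P.kD2b) * y[4]; // S_PKA -> S_OFF
  double f_pka_ad = P.kD3 * hill_act(AD, P.kD3a, P.kD3b) * y[4]; // S_PKA -> S_AD
  double f_ad_in  = P.kC1 * AD * y[0];              // S_OFF -> S_AD
  double f_ad_out = P.kC2 * hill_inh(AD, P.kC2a, P.kC2b) * y[5]; // S_AD -> S_OFF
  double f_adon   = P.kA1 * fiveHT * y[5];          // S_AD -> S_ADON
  double f_adon_r = P.kA2 * y[6];                   // S_ADON -> S_AD

  dy[1] = f_act - f_inact;
  dy[2] = f_inact - f_rec1 - f_sort;
  dy[3] = f_sort - f_rec2;
  dy[4] = f_pka_in - f_pka_out - f_pka_ad;
  dy[5] = f_ad_in - f_ad_out + f_pka_ad - f_adon + f_adon_r;
  dy[6] = f_adon - f_adon_r;
  dy[0] = -(dy[1] + dy[2] + dy[3] + dy[4] + dy[5] + dy[6]);

  dy[7] = P.kDAGp * (y[1] + y[6]) - P.kDAGd * y[7];
  dy[8] = P.Vm * (fiveHT > 0.0 ? fiveHT / (P.K5HT + fiveHT) : 0.0) -
          P.kcAMPd * (y[8] - P.cAMP_basal);
  double diss = P.Kfpka * y[8] * y[11];
  double reas = P.Kbpka * y[9] * y[10];
  dy[9]  = diss - reas;
  dy[10] = diss - reas;
  dy[11] = reas - diss;

  double synAD = aniso ? 0.0 : P.kS1 * hill_act(ipkc, P.kS1a, P.kS1b);
  double synD  = aniso ? 0.0 : P.kS3 * hill_act(ipka, P.kS3a, P.kS3b);
  dy[12] = synAD - P.kS2 * y[12];
  dy[13] = synD  - P.kS4 * y[13];
}

// Linear interpolation of a cumulative-integral series stored on the solver
// grid; exact at nodes, O(dt^2) between them.
static inline double q_at(const std::vector<double>& q, double tt, double dt,
                          int imax) {
  if (tt <= 0.0) return 0.0;
  double x = tt / dt;
  if (x >= imax) return q[imax];
  int i0 = (int)std::floor(x);
  double fr = x - i0;
  return q[i0] + fr * (q[i0 + 1] - q[i0]);
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector state, double fiveHT, bool aniso, bool kt,
                      double ipkc, double ipka, NumericVector params) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  Pars P = unpack(params);
  std::vector<double> y(state.begin(), state.end());
  NumericVector out(NSTATE);
  deriv(y.data(), fiveHT, aniso, kt, ipkc, ipka, P, REAL(out));
  out.names() = state.names();
  return out;
}

// Fixed-step RK4 with per-step refresh of the two trapezoid history
// integrals. Stimulus and drug inputs are piecewise constant on the grid
// (value on [t_i, t_{i+1})); the history integrals are evaluated at the
// start of each step and held over its four stages.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector init, NumericVector params,
                  NumericVector fiveHT, LogicalVector aniso, LogicalVector kt,
                  double dt, int n) {
  if (init.size() != NSTATE) stop("init must have %d components", NSTATE);
  if (fiveHT.size() != n || aniso.size() != n || kt.size() != n)
    stop("input vectors must have length n = %d", n);
  if (dt <= 0) stop("dt must be positive");
  Pars P = unpack(params);

  NumericMatrix out(n + 1, NSTATE);
  NumericVector ipkc_out(n + 1), ipka_out(n + 1);
  std::vector<double> qDAG(n + 1, 0.0), qC(n + 1, 0.0);
  std::vector<double> y(init.begin(), init.end());
  for (int j = 0; j < NSTATE; ++j) out(0, j) = y[j];

  std::vector<double> k1(NSTATE), k2(NSTATE), k3(NSTATE), k4(NSTATE),
      tmp(NSTATE);

  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    // windowed integral of PKC activity (DAG) over [t - intPKC, t]
    double ipkc = q_at(qDAG, t, dt, i) - q_at(qDAG, t - P.intPKC, dt, i);
    // delayed windowed integral of PKA activity over
    // [t - delayD - intPKA, t - delayD]
    double ipka = q_at(qC, t - P.delayD, dt, i) -
                  q_at(qC, t - P.delayD - P.intPKA, dt, i);
    ipkc_out[i] = ipkc;
    ipka_out[i] = ipka;

    double u = fiveHT[i];
    bool an = aniso[i], k5 = kt[i];

    deriv(y.data(), u, an, k5, ipkc, ipka, P, k1.data());
    for (int j = 0; j < NSTATE; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    deriv(tmp.data(), u, an, k5, ipkc, ipka, P, k2.data());
    for (int j = 0; j < NSTATE; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    deriv(tmp.data(), u, an, k5, ipkc, ipka, P, k3.data());
    for (int j = 0; j < NSTATE; ++j) tmp[j] = y[j] + dt * k3[j];
    deriv(tmp.data(), u, an, k5, ipkc, ipka, P, k4.data());

    double C_old = k5 ? 0.0 : y[10], dag_old = y[7];
    for (int j = 0; j < NSTATE; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(y[j]))
        stop("state diverged (non-finite component %d) at step %d, t = %g min",
             j + 1, i + 1, (i + 1) * dt);
      out(i + 1, j) = y[j];
    }
    qDAG[i + 1] = qDAG[i] + 0.5 * dt * (dag_old + y[7]);
    double C_new = k5 ? 0.0 : y[10];
    qC[i + 1] = qC[i] + 0.5 * dt * (C_old + C_new);
  }
  double tn = n * dt;
  ipkc_out[n] = q_at(qDAG, tn, dt, n) - q_at(qDAG, tn - P.intPKC, dt, n);
  ipka_out[n] = q_at(qC, tn - P.delayD, dt, n) -
                q_at(qC, tn - P.delayD - P.intPKA, dt, n);

  return List::create(_["state"] = out, _["ipkc"] = ipkc_out,
                      _["ipka"] = ipka_out);
}
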