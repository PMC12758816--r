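#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for the modified Epileptor-2 vector field with
// impulsive stimulation (instantaneous jumps of V at pulse grid steps) and
// time-varying bath potassium. The slow (ion) equations may be scaled by a
// factor eps_slow for slow-passage analysis of the fast subsystem.

struct Params {
  double gamma, dK, dNa, dx, Ko0, Nai0, tauK, tauNa, taum, taux,
         rho, gK, gexc, ginh, Vinh, Vth, numax, nernst;
};

static inline double frate(double V, const Params &p) {
  // numax / (1 + exp(Vth - V)); exp overflow -> Inf -> rate 0, which is exact
  return p.numax / (1.0 + std::exp(p.Vth - V));
}

static inline double pump(double K, double Na, const Params &p) {
  return p.rho / ((1.0 + std::exp(3.5 - K)) * (1.0 + std::exp((25.0 - Na) / 3.0)));
}

// Bath potassium schedule: mode 0 constant, 1 piecewise-constant (LOCF over
// breakpoints), 2 piecewise-linear interpolation with flat extrapolation.
struct KbathSchedule {
  int mode;
  const double *t, *v;
  int n;
  double at(double time) const {
    if (mode == 0 || n == 1) return v[0];
    if (time <= t[0]) return v[0];
    if (time >= t[n - 1]) return v[n - 1];
    int i = 0;
    while (i + 1 < n && t[i + 1] <= time) ++i;
    if (mode == 1) return v[i];
    // linear
    double w = (time - t[i]) / (t[i + 1] - t[i]);
    return v[i] + w * (v[i + 1] - v[i]);
  }
};

static inline void deriv(const double *s, double t, const Params &p,
                         const KbathSchedule &kb, double eps_slow, double *d) {
  const double V = s[0], x = s[1], K = s[2], Na = s[3];
  const double nu = frate(V, p);
  const double u = p.gK * p.nernst * std::log(K / p.Ko0) + p.gexc * nu * x +
                   p.ginh * (p.Vinh - V);
  const double Ip = pump(K, Na, p);
  d[0] = (u - V) / p.taum;
  d[1] = (1.0 - x) / p.taux - p.dx * x * nu;
  d[2] = eps_slow * ((kb.at(t) - K) / p.tauK - 2.0 * p.gamma * Ip + p.dK * nu);
  d[3] = eps_slow * ((p.Nai0 - Na) / p.tauNa - 3.0 * Ip + p.dNa * nu);
}

// [[Rcpp::export]]
List rk4_integrate(NumericVector par, NumericVector init, int n_steps, double dt,
                   IntegerVector pulse_step, NumericVector pulse_dv,
                   int kb_mode, NumericVector kb_t, NumericVector kb_v,
                   double eps_slow, int record_every) {
  Params p;
  p.gamma = par[0];  p.dK = par[1];   p.dNa = par[2];  p.dx = par[3];
  p.Ko0 = par[4];    p.Nai0 = par[5]; p.tauK = par[6]; p.tauNa = par[7];
  p.taum = par[8];   p.taux = par[9]; p.rho = par[10]; p.gK = par[11];
  p.gexc = par[12];  p.ginh = par[13]; p.Vinh = par[14]; p.Vth = par[15];
  p.numax = par[16]; p.nernst = par[17];

  KbathSchedule kb;
  kb.mode = kb_mode;
  kb.t = kb_t.begin();
  kb.v = kb_v.begin();
  kb.n = kb_v.size();

  double s[4] = { init[0], init[1], init[2], init[3] };
  double k1[4], k2[4], k3[4], k4[4], tmp[4];

  const int n_rec = n_steps / record_every + 1;
  NumericVector rt(n_rec), rV(n_rec), rx(n_rec), rK(n_rec), rNa(n_rec);

  const int np = pulse_step.size();
  int pi = 0, ri = 0;

  for (int i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    while (pi < np && pulse_step[pi] == i) {
      s[0] += pulse_dv[pi];
      ++pi;
    }
    if (i % record_every == 0 && ri < n_rec) {
      rt[ri] = t; rV[ri] = s[0]; rx[ri] = s[1]; rK[ri] = s[2]; rNa[ri] = s[3];
      ++ri;
    }
    if (i == n_steps) break;

    deriv(s, t, p, kb, eps_slow, k1);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    deriv(tmp, t + 0.5 * dt, p, kb, eps_slow, k2);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    deriv(tmp, t + 0.5 * dt, p, kb, eps_slow, k3);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt * k3[j];
    deriv(tmp, t + dt, p, kb, eps_slow, k4);
    for (int j = 0; j < 4; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    if (!(std::isfinite(s[0]) && std::isfinite(s[1]) && s[2] > 0.0 && s[3] > 0.0))
      stop("state left the admissible set at t = %f s (V=%f, K_o=%f, Na_i=%f)",
           t + dt, s[0], s[2], s[3]);
  }

  return List::create(_["time"] = rt, _["V"] = rV, _["x_D"] = rx,
                      _["K_o"] = rK, _["Na_i"] = rNa,
                      _["final_state"] = NumericVector::create(s[0], s[1], s[2], s[3]));
}
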