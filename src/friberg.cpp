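#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Transit-compartment model of thrombopoiesis:
//   dP/dt  = k*P*(1 - E(t))*(C0/C)^gamma - k*P
//   dTj/dt = k*(T_{j-1} - T_j),  j = 1..3, T_0 = P
//   dC/dt  = k*T3 - k*C
// with k = 4/MTT and E(t) the step-wise toxicity: sum over active dose
// events of eeff * normalized_dose, each event active on
// [start, start + duration).

namespace {

struct Pars {
  double k, gamma, c0, eeff;
  bool clip;
};

inline void deriv(const double* y, double effect, const Pars& p, double* dy) {
  double feedback = std::pow(p.c0 / std::max(y[4], 1e-12), p.gamma);
  dy[0] = p.k * y[0] * (1.0 - effect) * feedback - p.k * y[0];
  dy[1] = p.k * (y[0] - y[1]);
  dy[2] = p.k * (y[1] - y[2]);
  dy[3] = p.k * (y[2] - y[3]);
  dy[4] = p.k * y[3] - p.k * y[4];
}

inline void rk4_step(double* y, double hstep, double effect, const Pars& p) {
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  deriv(y, effect, p, k1);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * hstep * k1[i];
  deriv(tmp, effect, p, k2);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * hstep * k2[i];
  deriv(tmp, effect, p, k3);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + hstep * k3[i];
  deriv(tmp, effect, p, k4);
  for (int i = 0; i < 5; ++i)
    y[i] += hstep / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// toxicity effect at time t (piecewise constant between breakpoints)
inline double effect_at(double t, const NumericMatrix& ev, double eeff,
                        bool clip) {
  double e = 0.0;
  for (int i = 0; i < ev.nrow(); ++i) {
    double s = ev(i, 0), d = ev(i, 1), dur = ev(i, 2);
    if (t >= s && t < s + dur) e += eeff * d;
  }
  if (clip && e > 1.0) e = 1.0;
  return e;
}

}  // namespace

// [[Rcpp::export(name = ".friberg_simulate_cpp")]]
NumericMatrix friberg_simulate_cpp(NumericVector par, NumericMatrix events,
                                   NumericVector times, double h,
                                   bool clip_effect) {
  double mtt = par[0], gamma = par[1], c0 = par[2], eeff = par[3];
  Pars p{4.0 / mtt, gamma, c0, eeff, clip_effect};

  int nt = times.size();
  NumericMatrix out(nt, 5);

  // breakpoints: event starts/ends + output times; RHS smooth in between
  std::vector<double> brk;
  brk.reserve(2 * events.nrow() + nt + 1);
  brk.push_back(0.0);
  for (int i = 0; i < events.nrow(); ++i) {
    brk.push_back(events(i, 0));
    brk.push_back(events(i, 0) + events(i, 2));
  }
  for (int i = 0; i < nt; ++i) brk.push_back(times[i]);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            brk.end());

  double y[5] = {c0, c0, c0, c0, c0};  // steady state at C0
  double t = 0.0;
  int iout = 0;
  // times are required sorted and >= 0; record t=0 outputs
  while (iout < nt && times[iout] <= 1e-12) {
    for (int j = 0; j < 5; ++j) out(iout, j) = y[j];
    ++iout;
  }
  double tmax = times[nt - 1];
  for (size_t b = 0; b + 1 < brk.size() && t < tmax; ++b) {
    double t0 = brk[b], t1 = brk[b + 1];
    if (t1 <= t + 1e-12) continue;
    t0 = t;
    double span = t1 - t0;
    int nstep = std::max(1, (int)std::ceil(span / h));
    double hstep = span / nstep;
    double eff = effect_at(0.5 * (t0 + t1), events, eeff, clip_effect);
    for (int s = 0; s < nstep; ++s) {
      rk4_step(y, hstep, eff, p);
      if (!std::isfinite(y[4]))
        stop("integration produced non-finite state at t=%f (mtt=%f gamma=%f c0=%f eeff=%f)",
             t0 + (s + 1) * hstep, mtt, gamma, c0, eeff);
    }
    t = t1;
    while (iout < nt && times[iout] <= t + 1e-12) {
      for (int j = 0; j < 5; ++j) out(iout, j) = y[j];
      ++iout;
    }
  }
  return out;
}
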