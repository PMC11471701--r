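#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// NARX cores. One closed-loop (or teacher-forced) rollout over an integer
// daily grid, with the modified mean-squared error evaluated on
// log-transformed counts at observation days, and reverse-mode gradients
// through the full rollout (backpropagation through time), including the
// exponential-smoothing output stage
//   s_0 = y_0,  s_i = alpha * y_i + (1 - alpha) * s_{i-1}
// whose smoothing factor alpha is a trainable parameter stored as a logit.
//
// Parameter vector layouts (column-major matrices, H = hidden size):
//   GRU (n_in = 2: previous scaled count, dose):
//     Wz[H*2] Uz[H*H] bz[H] Wr[H*2] Ur[H*H] br[H]
//     Wh[H*2] Uh[H*H] bh[H] wout[H] bout theta_alpha
//   FNN (n_in = D + 1: D delayed scaled counts, dose):
//     W1[H*n_in] b1[H] wout[H] bout theta_alpha
//
// Day 0 of the track is pinned to the scaled baseline; the network emits
// predictions for days 1..T. The raw (unsmoothed) output feeds the
// autoregressive delay line; the smoothed output is what is scored.

namespace {
inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }
}

// [[Rcpp::export(name = ".narx_run_cpp")]]
List narx_run_cpp(NumericVector par, int arch, int H, int D, int warmup,
                  int T, NumericVector u, double baseline_scaled,
                  IntegerVector obs_days, NumericVector obs_scaled,
                  NumericVector obs_log, double tlo, double inv_m,
                  double llow, bool teacher_force, NumericMatrix noise,
                  NumericVector drop_mask, bool want_grad) {
  const int n_in = (arch == 1) ? 2 : D + 1;
  const bool has_noise = noise.nrow() == T;
  const int npar = par.size();

  // offsets into the parameter vector
  int oWz = 0, oUz = 0, obz = 0, oWr = 0, oUr = 0, obr = 0, oWh = 0, oUh = 0,
      obh = 0, oW1 = 0, ob1 = 0, owout = 0, obout = 0, ota = 0;
  if (arch == 1) {
    oWz = 0;
    oUz = oWz + H * n_in;
    obz = oUz + H * H;
    oWr = obz + H;
    oUr = oWr + H * n_in;
    obr = oUr + H * H;
    oWh = obr + H;
    oUh = oWh + H * n_in;
    obh = oUh + H * H;
    owout = obh + H;
  } else {
    oW1 = 0;
    ob1 = oW1 + H * n_in;
    owout = ob1 + H;
  }
  obout = owout + H;
  ota = obout + 1;
  if (ota + 1 != npar) stop("parameter vector has wrong length");

  const double* P = &par[0];
  const double alpha = sigm(P[ota]);

  // observation lookup by day
  std::vector<int> obs_idx(T + 1, -1);
  for (int j = 0; j < obs_days.size(); ++j) {
    int d = obs_days[j];
    if (d < 0 || d > T) stop("observation day %d outside track horizon", d);
    obs_idx[d] = j;
  }

  std::vector<double> y(T + 1), s(T + 1);
  y[0] = baseline_scaled;

  // feedback value entering the delay line for day d
  auto fbv = [&](int d) -> double {
    if (d < 0) return baseline_scaled;
    if (teacher_force && obs_idx[d] >= 0) return obs_scaled[obs_idx[d]];
    return y[d];
  };

  const int nsteps = ((arch == 1) ? warmup : 0) + T;  // FNN needs no warmup
  const int wsteps = (arch == 1) ? warmup : 0;

  // per-step storage for backward
  std::vector<double> Xs((size_t)nsteps * n_in);
  std::vector<double> Zs, Rs, HHs, Hs, As;
  if (arch == 1) {
    Zs.assign((size_t)nsteps * H, 0.0);
    Rs.assign((size_t)nsteps * H, 0.0);
    HHs.assign((size_t)nsteps * H, 0.0);
    Hs.assign((size_t)(nsteps + 1) * H, 0.0);  // Hs[0] = h0 = 0
  } else {
    As.assign((size_t)nsteps * H, 0.0);
  }

  // ---------- forward ----------
  for (int st = 0; st < nsteps; ++st) {
    const int t = st - wsteps + 1;  // day being predicted; t <= 0 -> warmup
    double* x = &Xs[(size_t)st * n_in];
    if (arch == 1) {
      x[0] = (t <= 0) ? baseline_scaled : fbv(t - 1);
      x[1] = (t <= 0) ? 0.0 : u[t - 1];
    } else {
      for (int k = 0; k < D; ++k) x[k] = fbv(t - 1 - k);
      x[D] = u[t - 1];
    }
    if (t >= 1 && has_noise)
      for (int k = 0; k < n_in; ++k) x[k] += noise(t - 1, k);

    if (arch == 1) {
      const double* hprev = &Hs[(size_t)st * H];
      double* z = &Zs[(size_t)st * H];
      double* r = &Rs[(size_t)st * H];
      double* hh = &HHs[(size_t)st * H];
      double* h = &Hs[(size_t)(st + 1) * H];
      for (int i = 0; i < H; ++i) {
        double az = P[obz + i], ar = P[obr + i];
        for (int k = 0; k < n_in; ++k) {
          az += P[oWz + i + H * k] * x[k];
          ar += P[oWr + i + H * k] * x[k];
        }
        for (int j = 0; j < H; ++j) {
          az += P[oUz + i + H * j] * hprev[j];
          ar += P[oUr + i + H * j] * hprev[j];
        }
        z[i] = sigm(az);
        r[i] = sigm(ar);
      }
      for (int i = 0; i < H; ++i) {
        double ah = P[obh + i];
        for (int k = 0; k < n_in; ++k) ah += P[oWh + i + H * k] * x[k];
        for (int j = 0; j < H; ++j)
          ah += P[oUh + i + H * j] * (r[j] * hprev[j]);
        hh[i] = std::tanh(ah);
        h[i] = (1.0 - z[i]) * hprev[i] + z[i] * hh[i];
      }
      if (t >= 1) {
        double yt = P[obout];
        for (int i = 0; i < H; ++i)
          yt += P[owout + i] * h[i] * drop_mask[i];
        if (!std::isfinite(yt)) stop("non-finite network output at day %d", t);
        y[t] = yt;
      }
    } else {
      double* a = &As[(size_t)st * H];
      double yt = P[obout];
      for (int i = 0; i < H; ++i) {
        double ai = P[ob1 + i];
        for (int k = 0; k < n_in; ++k) ai += P[oW1 + i + H * k] * x[k];
        a[i] = std::tanh(ai);
        yt += P[owout + i] * a[i] * drop_mask[i];
      }
      if (!std::isfinite(yt)) stop("non-finite network output at day %d", t);
      y[t] = yt;
    }
  }

  // smoothing
  s[0] = y[0];
  for (int t = 1; t <= T; ++t) s[t] = alpha * y[t] + (1.0 - alpha) * s[t - 1];

  // ---------- loss (SMSE on log counts) ----------
  const int N = obs_days.size();
  double loss = 0.0;
  std::vector<double> g_s(T + 1, 0.0);
  for (int j = 0; j < N; ++j) {
    int i = obs_days[j];
    double rsame = obs_log[j] - (llow + (s[i] - tlo) * inv_m);
    loss += rsame * rsame;
    if (want_grad) g_s[i] += -2.0 * rsame * inv_m;
    if (i - 1 >= 0) {
      double rr = obs_log[j] - (llow + (s[i - 1] - tlo) * inv_m);
      loss += 0.3 * rr * rr;
      if (want_grad) g_s[i - 1] += -0.6 * rr * inv_m;
    }
    if (i + 1 <= T) {
      double rr = obs_log[j] - (llow + (s[i + 1] - tlo) * inv_m);
      loss += 0.3 * rr * rr;
      if (want_grad) g_s[i + 1] += -0.6 * rr * inv_m;
    }
  }
  if (N > 0) {
    loss /= N;
    if (want_grad)
      for (int i = 0; i <= T; ++i) g_s[i] /= N;
  }

  List out = List::create(_["y"] = NumericVector(y.begin(), y.end()),
                          _["s"] = NumericVector(s.begin(), s.end()),
                          _["loss"] = loss, _["alpha"] = alpha,
                          _["n_obs"] = N);
  if (!want_grad) return out;

  // ---------- backward ----------
  NumericVector grad(npar);
  double* G = &grad[0];
  std::vector<double> g_y(T + 1, 0.0);
  double g_alpha = 0.0;

  for (int t = T; t >= 1; --t) {
    g_y[t] += alpha * g_s[t];
    g_alpha += (y[t] - s[t - 1]) * g_s[t];
    g_s[t - 1] += (1.0 - alpha) * g_s[t];
  }
  // g_s[0] flows into y[0] = const baseline: dropped

  std::vector<double> g_h(H, 0.0), g_hprev(H), g_x(n_in);
  for (int st = nsteps - 1; st >= 0; --st) {
    const int t = st - wsteps + 1;
    const double* x = &Xs[(size_t)st * n_in];
    std::fill(g_x.begin(), g_x.end(), 0.0);

    if (arch == 1) {
      const double* hprev = &Hs[(size_t)st * H];
      const double* z = &Zs[(size_t)st * H];
      const double* r = &Rs[(size_t)st * H];
      const double* hh = &HHs[(size_t)st * H];
      const double* h = &Hs[(size_t)(st + 1) * H];
      if (t >= 1 && g_y[t] != 0.0) {
        for (int i = 0; i < H; ++i) {
          G[owout + i] += g_y[t] * h[i] * drop_mask[i];
          g_h[i] += g_y[t] * P[owout + i] * drop_mask[i];
        }
        G[obout] += g_y[t];
      }
      std::fill(g_hprev.begin(), g_hprev.end(), 0.0);
      std::vector<double> g_z(H), g_hh(H), g_rpre(H);
      for (int i = 0; i < H; ++i) {
        g_z[i] = g_h[i] * (hh[i] - hprev[i]) * z[i] * (1.0 - z[i]);
        g_hh[i] = g_h[i] * z[i] * (1.0 - hh[i] * hh[i]);
        g_hprev[i] += g_h[i] * (1.0 - z[i]);
      }
      // candidate path
      for (int i = 0; i < H; ++i) {
        G[obh + i] += g_hh[i];
        for (int k = 0; k < n_in; ++k) {
          G[oWh + i + H * k] += g_hh[i] * x[k];
          g_x[k] += P[oWh + i + H * k] * g_hh[i];
        }
      }
      for (int j = 0; j < H; ++j) {
        double g_rh = 0.0;
        for (int i = 0; i < H; ++i) {
          G[oUh + i + H * j] += g_hh[i] * (r[j] * hprev[j]);
          g_rh += P[oUh + i + H * j] * g_hh[i];
        }
        g_hprev[j] += g_rh * r[j];
        g_rpre[j] = g_rh * hprev[j] * r[j] * (1.0 - r[j]);
      }
      // gates
      for (int i = 0; i < H; ++i) {
        G[obr + i] += g_rpre[i];
        G[obz + i] += g_z[i];
        for (int k = 0; k < n_in; ++k) {
          G[oWr + i + H * k] += g_rpre[i] * x[k];
          G[oWz + i + H * k] += g_z[i] * x[k];
          g_x[k] += P[oWr + i + H * k] * g_rpre[i] +
                    P[oWz + i + H * k] * g_z[i];
        }
        for (int j = 0; j < H; ++j) {
          G[oUr + i + H * j] += g_rpre[i] * hprev[j];
          G[oUz + i + H * j] += g_z[i] * hprev[j];
        }
      }
      for (int j = 0; j < H; ++j) {
        double acc = 0.0;
        for (int i = 0; i < H; ++i)
          acc += P[oUr + i + H * j] * g_rpre[i] + P[oUz + i + H * j] * g_z[i];
        g_hprev[j] += acc;
      }
      // feedback into previous prediction
      if (t >= 2 && !(teacher_force && obs_idx[t - 1] >= 0))
        g_y[t - 1] += g_x[0];
      g_h = g_hprev;
    } else {
      const double* a = &As[(size_t)st * H];
      if (g_y[t] != 0.0) {
        G[obout] += g_y[t];
        for (int i = 0; i < H; ++i) {
          G[owout + i] += g_y[t] * a[i] * drop_mask[i];
          double g_pre = g_y[t] * P[owout + i] * drop_mask[i] *
                         (1.0 - a[i] * a[i]);
          G[ob1 + i] += g_pre;
          for (int k = 0; k < n_in; ++k) {
            G[oW1 + i + H * k] += g_pre * x[k];
            g_x[k] += P[oW1 + i + H * k] * g_pre;
          }
        }
        for (int k = 0; k < D; ++k) {
          int day = t - 1 - k;
          if (day >= 1 && !(teacher_force && obs_idx[day] >= 0))
            g_y[day] += g_x[k];
        }
      }
    }
  }
  G[ota] = g_alpha * alpha * (1.0 - alpha);
  out["grad"] = grad;
  return out;
}
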