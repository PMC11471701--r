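# shared fixtures and independent oracles

fix_schedule <- function(regimen = "d21_plain", n_cycles = 6, ...) {
  thrombonarx:::regimen_schedule(regimen, n_cycles, ...)
}

# independent reference integrator: plain fixed-step RK4 in R, effect
# evaluated from toxicity_effect() at substep midpoints
ref_rk4 <- function(params, schedule, horizon, h = 1e-3,
                    clip_effect = FALSE) {
  k <- 4 / params$mtt
  gam <- params$gamma
  c0 <- params$c0
  rhs <- function(y, eff) {
    fb <- (c0 / y[5])^gam
    c(
      k * y[1] * (1 - eff) * fb - k * y[1],
      k * (y[1] - y[2]), k * (y[2] - y[3]), k * (y[3] - y[4]),
      k * y[4] - k * y[5]
    )
  }
  nstep <- round(horizon / h)
  y <- rep(c0, 5)
  out <- matrix(NA_real_, horizon + 1, 5)
  out[1, ] <- y
  day_at <- 1
  for (s in seq_len(nstep)) {
    t0 <- (s - 1) * h
    eff <- toxicity_effect(schedule, params, t0 + h / 2)
    if (clip_effect) eff <- min(eff, 1)
    k1 <- rhs(y, eff)
    k2 <- rhs(y + h / 2 * k1, eff)
    k3 <- rhs(y + h / 2 * k2, eff)
    k4 <- rhs(y + h * k3, eff)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tnow <- s * h
    if (abs(tnow - round(tnow)) < h / 2 && round(tnow) >= day_at) {
      out[round(tnow) + 1, ] <- y
      day_at <- round(tnow) + 1
    }
  }
  list(days = 0:horizon, circ = out[, 5], state = out)
}

# brute-force double-loop evaluation of the modified MSE on log counts
smse_brute <- function(obs_day, obs_log, days, pred_log) {
  tot <- 0
  for (j in seq_along(obs_day)) {
    for (k in seq_along(days)) {
      if (days[k] == obs_day[j]) {
        tot <- tot + (obs_log[j] - pred_log[k])^2
      }
      if (days[k] == obs_day[j] - 1 || days[k] == obs_day[j] + 1) {
        tot <- tot + 0.3 * (obs_log[j] - pred_log[k])^2
      }
    }
  }
  tot / length(obs_day)
}

# series with a given number of counts per cycle at regular in-cycle offsets
fix_series_regular <- function(id, schedule, counts_per_cycle,
                               level = 200, transfusion = FALSE,
                               cycles = seq_len(schedule$n_cycles)) {
  win <- cycle_windows(schedule)
  days <- unlist(lapply(cycles, function(k) {
    n <- if (length(counts_per_cycle) == 1) {
      counts_per_cycle
    } else {
      counts_per_cycle[k]
    }
    if (n == 0) {
      return(numeric(0))
    }
    seq(win$from[k], win$to[k] - 1, length.out = n)
  }))
  patient_series(id, days, rep(level, length(days)),
    transfusion_flag = transfusion
  )
}

# constant-track helper on a daily grid
fix_track <- function(days, counts, arch = "gru") {
  tr <- scaling_transform(arch)
  sc <- scale_count(counts, tr)
  prediction_track(days, sc, sc, tr)
}
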