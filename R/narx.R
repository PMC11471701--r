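#' NARX network configuration
#'
#' Lean per-patient architectures: a one-hidden-layer tanh feed-forward
#' network fed by a tapped delay line of `n_delays` past (scaled) counts,
#' or a single-layer gated recurrent unit whose hidden state carries the
#' memory (one count lag suffices). Both receive the normalized dose of
#' the day being crossed as exogenous input and share a linear output map
#' plus a trainable exponential-smoothing stage.
#'
#' @param architecture `"gru"` or `"fnn"`.
#' @param n_delays tapped-delay-line length (used by the FNN; the GRU uses
#'   one lag).
#' @param hidden_size number of hidden units.
#' @param alpha_init initial smoothing factor in `[0, 1]`.
#' @param warmup_days steady-state days fed to the GRU before day 0 so the
#'   hidden state settles at the baseline fixed point.
#' @return An object of class `narx_config`.
#' @export
narx_config <- function(architecture = c("gru", "fnn"), n_delays = NULL,
                        hidden_size = 8, alpha_init = 0.5,
                        warmup_days = 7) {
  architecture <- match.arg(architecture)
  if (is.null(n_delays)) n_delays <- if (architecture == "fnn") 7L else 1L
  stopifnot(
    n_delays >= 1, hidden_size >= 1,
    alpha_init >= 0, alpha_init <= 1, warmup_days >= 0
  )
  structure(
    list(
      architecture = architecture, n_delays = as.integer(n_delays),
      hidden_size = as.integer(hidden_size), alpha_init = alpha_init,
      warmup_days = as.integer(warmup_days)
    ),
    class = "narx_config"
  )
}

# parameter-vector layout bookkeeping ---------------------------------------

narx_layout <- function(config) {
  H <- config$hidden_size
  n_in <- if (config$architecture == "gru") 2L else config$n_delays + 1L
  if (config$architecture == "gru") {
    sizes <- c(
      Wz = H * n_in, Uz = H * H, bz = H,
      Wr = H * n_in, Ur = H * H, br = H,
      Wh = H * n_in, Uh = H * H, bh = H,
      wout = H, bout = 1, theta_alpha = 1
    )
  } else {
    sizes <- c(
      W1 = H * n_in, b1 = H,
      wout = H, bout = 1, theta_alpha = 1
    )
  }
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(
    sizes = sizes, starts = starts, ends = ends,
    n_par = sum(sizes), n_in = n_in
  )
}

narx_slice <- function(config, block) {
  lay <- narx_layout(config)
  seq.int(lay$starts[[block]], lay$ends[[block]])
}

# indices of prunable weights (weight matrices and output weights, not
# biases, not the smoothing logit)
narx_prunable <- function(config) {
  blocks <- if (config$architecture == "gru") {
    c("Wz", "Uz", "Wr", "Ur", "Wh", "Uh", "wout")
  } else {
    c("W1", "wout")
  }
  unlist(lapply(blocks, narx_slice, config = config), use.names = FALSE)
}

# indices of the linear output map (the only part recalibration may touch)
narx_output_idx <- function(config) {
  c(narx_slice(config, "wout"), narx_slice(config, "bout"))
}

logit <- function(p) log(p / (1 - p))

#' Initialize a NARX model
#'
#' Weights are drawn uniformly within `1/sqrt(fan_in)` of zero (biases at
#' zero), which keeps the untrained closed loop stable near the baseline.
#'
#' @param config a [narx_config()].
#' @param transform a [scaling_transform()]; defaults to the one matching
#'   the architecture.
#' @param dose_scale positive scale by which normalized doses are divided
#'   before entering the network (typically the cohort maximum dose).
#' @param seed integer seed for the weight draw.
#' @return An object of class `narx_model` holding the flattened parameter
#'   vector `par`, the config and the scaling transform.
#' @export
narx_model <- function(config, transform = NULL, dose_scale = 1, seed = 1) {
  if (is.null(transform)) transform <- scaling_transform(config$architecture)
  stopifnot(dose_scale > 0)
  lay <- narx_layout(config)
  set.seed(as.integer(seed))
  par <- numeric(lay$n_par)
  H <- config$hidden_size
  for (blk in names(lay$sizes)) {
    idx <- seq.int(lay$starts[[blk]], lay$ends[[blk]])
    fan_in <- if (blk %in% c("Wz", "Wr", "Wh", "W1")) {
      lay$n_in
    } else if (blk %in% c("Uz", "Ur", "Uh", "wout")) {
      H
    } else {
      NA
    }
    if (!is.na(fan_in)) {
      par[idx] <- stats::runif(length(idx), -1, 1) / sqrt(fan_in)
    }
  }
  a <- min(max(config$alpha_init, 1e-6), 1 - 1e-6)
  par[narx_slice(config, "theta_alpha")] <- logit(a)
  structure(
    list(
      config = config, transform = transform,
      dose_scale = dose_scale, par = par
    ),
    class = "narx_model"
  )
}

#' Smoothing factor of a NARX model
#' @param model a [narx_model()].
#' @return `alpha` in `[0, 1]`.
#' @export
narx_alpha <- function(model) {
  stats::plogis(model$par[narx_slice(model$config, "theta_alpha")])
}

#' @export
print.narx_model <- function(x, ...) {
  cat(sprintf(
    "narx_model: ARX-%s, hidden %d, %d parameters, alpha=%.3f\n",
    toupper(x$config$architecture), x$config$hidden_size,
    length(x$par), narx_alpha(x)
  ))
  invisible(x)
}

# exogenous input series: dose administered during (t-1, t], t = 1..horizon
dose_input <- function(schedule, horizon, dose_scale = 1) {
  u <- numeric(horizon)
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    from <- ev$start_day[i]
    to <- from + ev$duration_days[i]
    days <- seq_len(horizon) - 1 # interval (t-1, t] indexed by its start day
    active <- days >= floor(from) & days < to
    u[active] <- u[active] + ev$normalized_dose[i]
  }
  u / dose_scale
}

# shared low-level rollout; obs on the daily grid (rounded), in scaled and
# log space; returns the raw C++ result
narx_rollout <- function(model, baseline_count, schedule, horizon,
                         observations = NULL, teacher_forcing = FALSE,
                         noise = NULL, drop_mask = NULL, want_grad = FALSE) {
  cfg <- model$config
  tr <- model$transform
  if (is.null(observations)) {
    obs_days <- integer(0)
    obs_scaled <- numeric(0)
    obs_log <- numeric(0)
  } else {
    d <- as.integer(round(observations$observations$day))
    keep <- d >= 0 & d <= horizon
    d <- d[keep]
    cnt <- observations$observations$count[keep]
    # one observation per day (keep the first)
    first <- !duplicated(d)
    obs_days <- d[first]
    obs_scaled <- scale_count(cnt[first], tr)
    obs_log <- log(cnt[first])
  }
  if (is.null(noise)) noise <- matrix(numeric(), 0, 0)
  if (is.null(drop_mask)) drop_mask <- rep(1, cfg$hidden_size)
  .narx_run_cpp(
    model$par,
    arch = if (cfg$architecture == "gru") 1L else 0L,
    H = cfg$hidden_size, D = cfg$n_delays, warmup = cfg$warmup_days,
    T = as.integer(horizon),
    u = dose_input(schedule, horizon, model$dose_scale),
    baseline_scaled = scale_count(baseline_count, tr),
    obs_days = obs_days, obs_scaled = obs_scaled, obs_log = obs_log,
    tlo = tr$target_low, inv_m = 1 / tr$slope,
    llow = log(tr$lower_count),
    teacher_force = isTRUE(teacher_forcing),
    noise = noise, drop_mask = drop_mask, want_grad = want_grad
  )
}

#' Closed-loop daily prediction of a platelet time course
#'
#' The delay line (and, for the GRU, the hidden state via a steady-state
#' warm-up) is initialized at the scaled baseline; the network then steps
#' day by day, feeding its own raw output back while the exponentially
#' smoothed output forms the reported prediction. When `observations` are
#' supplied with `teacher_forcing = TRUE`, observed scaled counts replace
#' the feedback at measured days (training wiring).
#'
#' @param model a [narx_model()].
#' @param baseline_count baseline platelet count, 1e9 cells/l.
#' @param schedule a [therapy_schedule()].
#' @param horizon prediction horizon in days (track covers days
#'   `0:horizon`).
#' @param observations optional [patient_series()] for teacher forcing.
#' @param teacher_forcing replace feedback by observations at measured days.
#' @return A `prediction_track`: `days`, `raw` and `smoothed` (scaled
#'   space) and `counts` (1e9 cells/l).
#' @export
predict_closed_loop <- function(model, baseline_count, schedule, horizon,
                                observations = NULL,
                                teacher_forcing = FALSE) {
  stopifnot(horizon >= 1, baseline_count > 0)
  sched_end <- if (nrow(schedule$events)) {
    max(schedule$events$start_day + schedule$events$duration_days)
  } else {
    0
  }
  if (horizon < sched_end) {
    warning("prediction horizon ends before the last scheduled dose")
  }
  res <- narx_rollout(model, baseline_count, schedule, horizon,
    observations = observations, teacher_forcing = teacher_forcing
  )
  prediction_track(0:horizon, res$y, res$s, model$transform)
}

#' Construct a prediction track
#'
#' @param days integer daily grid.
#' @param raw regressed (unsmoothed) predictions in scaled space.
#' @param smoothed exponentially smoothed predictions in scaled space.
#' @param transform the [scaling_transform()] used to recover counts.
#' @return An object of class `prediction_track`.
#' @export
prediction_track <- function(days, raw, smoothed, transform) {
  stopifnot(
    length(days) == length(raw), length(raw) == length(smoothed),
    isTRUE(all.equal(smoothed[1], raw[1]))
  )
  counts <- inverse_scale(smoothed, transform)
  stopifnot(all(counts > 0))
  structure(
    list(days = days, raw = raw, smoothed = smoothed, counts = counts),
    class = "prediction_track"
  )
}

#' @export
print.prediction_track <- function(x, ...) {
  cat(sprintf(
    "prediction_track: days %d..%d, count range [%.3g, %.3g] e9/l\n",
    min(x$days), max(x$days), min(x$counts), max(x$counts)
  ))
  invisible(x)
}

#' Magnitude-based unstructured pruning
#'
#' Zeroes the `ceiling(fraction * n)` smallest-magnitude prunable weights
#' (weight matrices and output weights; biases and the smoothing factor
#' are kept).
#'
#' @param model a [narx_model()].
#' @param fraction fraction of prunable weights to remove, in `[0, 1)`.
#' @return The pruned model.
#' @export
prune_weights <- function(model, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) {
    return(model)
  }
  idx <- narx_prunable(model$config)
  k <- ceiling(fraction * length(idx))
  ord <- idx[order(abs(model$par[idx]))]
  model$par[ord[seq_len(k)]] <- 0
  model
}
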