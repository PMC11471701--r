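#' Training configuration for NARX models
#'
#' Two learning modes are supported. With transfer learning (`"tl"`), the
#' network is pre-trained on trajectories simulated from the patient's
#' fitted mechanistic model, then only the linear output map is
#' recalibrated on the real counts, and finally the whole network is
#' fine-tuned at a lower learning rate. Without transfer learning
#' (`"no_tl"`), a single stage trains on the real counts with dropout.
#' Gaussian input noise augments only the stages that see real patient
#' data; magnitude pruning is applied once, after the final stage.
#'
#' @param mode `"tl"` or `"no_tl"`.
#' @param learning_rate_pretrain,learning_rate_recalibrate,learning_rate_finetune
#'   positive learning rates; the fine-tuning rate must be lower than the
#'   pre-training rate.
#' @param weight_decay non-negative L2 penalty on the network weights
#'   (biases and the smoothing factor excluded).
#' @param smoothness_penalty_weight non-negative weight of the `alpha^2`
#'   penalty favouring strong exponential smoothing.
#' @param input_noise_sd standard deviation of the Gaussian noise added to
#'   scaled network inputs during real-data training stages.
#' @param dropout_rate hidden-unit dropout probability in `[0, 1)`; used
#'   only in `"no_tl"` mode.
#' @param pruning_fraction fraction of smallest-magnitude weights zeroed
#'   after the final stage, in `[0, 1)`.
#' @param epochs_pretrain,epochs_recalibrate,epochs_finetune,epochs_no_tl
#'   epoch budgets per stage.
#' @param grad_clip global gradient-norm clip.
#' @param seed integer seed for noise, dropout and weight initialization.
#' @return An object of class `training_config`.
#' @export
training_config <- function(mode = c("tl", "no_tl"),
                            learning_rate_pretrain = 1e-2,
                            learning_rate_recalibrate = 1e-2,
                            learning_rate_finetune = 1e-3,
                            weight_decay = 1e-4,
                            smoothness_penalty_weight = 0.05,
                            input_noise_sd = 0.05,
                            dropout_rate = 0.2,
                            pruning_fraction = 0.1,
                            epochs_pretrain = 500,
                            epochs_recalibrate = 200,
                            epochs_finetune = 200,
                            epochs_no_tl = 500,
                            grad_clip = 5,
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    learning_rate_pretrain > 0, learning_rate_recalibrate > 0,
    learning_rate_finetune > 0,
    learning_rate_finetune < learning_rate_pretrain,
    weight_decay >= 0, smoothness_penalty_weight >= 0,
    input_noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1,
    pruning_fraction >= 0, pruning_fraction < 1,
    epochs_pretrain >= 1, epochs_recalibrate >= 1, epochs_finetune >= 1,
    epochs_no_tl >= 1, grad_clip > 0
  )
  structure(
    list(
      mode = mode,
      learning_rate_pretrain = learning_rate_pretrain,
      learning_rate_recalibrate = learning_rate_recalibrate,
      learning_rate_finetune = learning_rate_finetune,
      weight_decay = weight_decay,
      smoothness_penalty_weight = smoothness_penalty_weight,
      input_noise_sd = input_noise_sd,
      dropout_rate = dropout_rate,
      pruning_fraction = pruning_fraction,
      epochs_pretrain = as.integer(epochs_pretrain),
      epochs_recalibrate = as.integer(epochs_recalibrate),
      epochs_finetune = as.integer(epochs_finetune),
      epochs_no_tl = as.integer(epochs_no_tl),
      grad_clip = grad_clip,
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Training objective of a NARX model
#'
#' `SMSE + weight_decay * sum(w^2) + smoothness_penalty_weight * alpha^2`,
#' where the weight-decay sum runs over the network weight matrices and
#' output weights (biases and the smoothing logit excluded) and the
#' smoothness penalty pushes `alpha` towards heavy smoothing.
#'
#' @param track a `prediction_track`.
#' @param series a [patient_series()] with observations inside the track.
#' @param model a [narx_model()].
#' @param cfg a [training_config()].
#' @return Finite scalar loss.
#' @export
objective <- function(track, series, model, cfg) {
  w <- model$par[narx_prunable(model$config)]
  a <- narx_alpha(model)
  smse(series, track) +
    cfg$weight_decay * sum(w^2) +
    cfg$smoothness_penalty_weight * a^2
}

#' Therapy scenarios for transfer-learning pre-training
#'
#' Simulates the patient's fitted mechanistic model under the actually
#' given schedule plus systematic variants: dose scalings (0, 0.5, 0.75,
#' 1.25, 1.5), shifts of all cycle starts after the first by +3/-3 days
#' (therapy delays), and single-cycle omissions. The first `n_variants`
#' entries of this fixed catalogue are used.
#'
#' @param params a [friberg_params()] (typically fitted).
#' @param actual the actually given [therapy_schedule()].
#' @param n_variants number of variants beside the actual schedule.
#' @param seed kept for reproducibility of any super-catalogue sampling;
#'   the catalogue itself is deterministic.
#' @param horizon simulation horizon; defaults to the end of the last
#'   cycle.
#' @return An object of class `scenario_set`: list of
#'   `list(schedule, trajectory)`, the actual schedule first.
#' @export
make_scenarios <- function(params, actual, n_variants = 7, seed = 1,
                           horizon = NULL) {
  stopifnot(n_variants >= 0)
  if (is.null(horizon)) {
    horizon <- ceiling(max(actual$cycle_start_days) + actual$cycle_length_days)
  }
  catalogue <- list()
  for (f in c(0, 0.5, 0.75, 1.25, 1.5)) {
    catalogue <- c(catalogue, list(scenario_schedule(actual, "dose", f)))
  }
  for (sh in c(3, -3)) {
    catalogue <- c(catalogue, list(scenario_schedule(actual, "shift", sh)))
  }
  for (k in seq_len(actual$n_cycles)[-1]) {
    catalogue <- c(catalogue, list(scenario_schedule(actual, "omit", k)))
  }
  n_variants <- min(n_variants, length(catalogue))
  schedules <- c(list(actual), catalogue[seq_len(n_variants)])
  out <- lapply(seq_along(schedules), function(i) {
    tr <- tryCatch(
      simulate_friberg(params, schedules[[i]], horizon = horizon),
      error = function(e) {
        stop(sprintf("scenario %d failed: %s", i, conditionMessage(e)))
      }
    )
    list(schedule = schedules[[i]], trajectory = tr)
  })
  structure(out, class = "scenario_set", horizon = horizon)
}

# build a variant schedule: dose scaling, cycle-start shift, cycle omission
scenario_schedule <- function(sched, type, value) {
  ev <- sched$events
  starts <- sched$cycle_start_days
  ends <- c(starts[-1], Inf)
  ev_cycle <- vapply(ev$start_day, function(d) {
    which(d >= starts & d < ends)[1]
  }, integer(1))
  if (type == "dose") {
    ev$normalized_dose <- ev$normalized_dose * value
  } else if (type == "shift") {
    move <- ev_cycle >= 2
    ev$start_day[move] <- ev$start_day[move] + value
    starts[-1] <- starts[-1] + value
    if (is.unsorted(starts)) starts <- sort(starts)
  } else if (type == "omit") {
    ev <- ev[ev_cycle != value, , drop = FALSE]
  }
  therapy_schedule(ev, sched$cycle_length_days, sched$n_cycles,
    cycle_start_days = starts
  )
}

# ---------------------------------------------------------------------------
# low-level staged trainer (Adam, per-epoch noise/dropout, checkpoint on the
# best noise-free closed-loop loss)

narx_prepare_target <- function(model, target) {
  cfg <- model$config
  tr <- model$transform
  obs <- target$series$observations
  d <- as.integer(round(obs$day))
  keep <- d >= 0 & d <= target$horizon
  d <- d[keep]
  cnt <- obs$count[keep]
  first <- !duplicated(d)
  list(
    u = dose_input(target$schedule, target$horizon, model$dose_scale),
    baseline_scaled = scale_count(target$baseline_count, tr),
    obs_days = d[first],
    obs_scaled = scale_count(cnt[first], tr),
    obs_log = log(cnt[first]),
    horizon = as.integer(target$horizon)
  )
}

narx_eval_prepared <- function(par, model, prep, teacher_force = FALSE,
                               noise = NULL, drop_mask = NULL,
                               want_grad = FALSE) {
  cfg <- model$config
  tr <- model$transform
  if (is.null(noise)) noise <- matrix(numeric(), 0, 0)
  if (is.null(drop_mask)) drop_mask <- rep(1, cfg$hidden_size)
  .narx_run_cpp(
    par,
    arch = if (cfg$architecture == "gru") 1L else 0L,
    H = cfg$hidden_size, D = cfg$n_delays, warmup = cfg$warmup_days,
    T = prep$horizon, u = prep$u, baseline_scaled = prep$baseline_scaled,
    obs_days = prep$obs_days, obs_scaled = prep$obs_scaled,
    obs_log = prep$obs_log,
    tlo = tr$target_low, inv_m = 1 / tr$slope, llow = log(tr$lower_count),
    teacher_force = teacher_force, noise = noise, drop_mask = drop_mask,
    want_grad = want_grad
  )
}

narx_train_stage <- function(model, targets, epochs, lr, cfg,
                             stage = "train",
                             noise_sd = 0, dropout_rate = 0,
                             trainable = NULL,
                             teacher_force = "mixed", seed = 1) {
  ncfg <- model$config
  lay <- narx_layout(ncfg)
  npar <- lay$n_par
  decay_idx <- narx_prunable(ncfg)
  ta_idx <- narx_slice(ncfg, "theta_alpha")
  if (is.null(trainable)) trainable <- seq_len(npar)
  frozen <- setdiff(seq_len(npar), trainable)

  preps <- lapply(targets, narx_prepare_target, model = model)
  H <- ncfg$hidden_size
  n_in <- lay$n_in

  penalized <- function(par, base_loss) {
    a <- stats::plogis(par[ta_idx])
    base_loss + cfg$weight_decay * sum(par[decay_idx]^2) +
      cfg$smoothness_penalty_weight * a^2
  }
  clean_loss <- function(par) {
    base <- mean(vapply(preps, function(pp) {
      narx_eval_prepared(par, model, pp, teacher_force = FALSE)$loss
    }, numeric(1)))
    penalized(par, base)
  }

  set.seed(as.integer(seed))
  par <- model$par
  m <- numeric(npar)
  v <- numeric(npar)
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  best_par <- par
  best_loss <- clean_loss(par)
  history <- data.frame(
    stage = character(0), epoch = integer(0),
    loss = numeric(0), alpha = numeric(0)
  )

  for (e in seq_len(epochs)) {
    tf <- switch(teacher_force,
      mixed = e <= ceiling(epochs / 2),
      always = TRUE,
      never = FALSE
    )
    g <- numeric(npar)
    tot <- 0
    for (pp in preps) {
      noise <- if (noise_sd > 0) {
        matrix(stats::rnorm(pp$horizon * n_in, sd = noise_sd),
          pp$horizon, n_in
        )
      } else {
        NULL
      }
      mask <- if (dropout_rate > 0) {
        stats::rbinom(H, 1, 1 - dropout_rate) / (1 - dropout_rate)
      } else {
        NULL
      }
      res <- narx_eval_prepared(par, model, pp,
        teacher_force = tf,
        noise = noise, drop_mask = mask, want_grad = TRUE
      )
      g <- g + res$grad
      tot <- tot + res$loss
    }
    g <- g / length(preps)
    tot <- tot / length(preps)
    # penalty gradients
    g[decay_idx] <- g[decay_idx] + 2 * cfg$weight_decay * par[decay_idx]
    a <- stats::plogis(par[ta_idx])
    g[ta_idx] <- g[ta_idx] +
      2 * cfg$smoothness_penalty_weight * a * a * (1 - a)
    if (length(frozen)) g[frozen] <- 0
    if (!all(is.finite(g)) || !is.finite(tot)) {
      warning(sprintf(
        "%s stage diverged at epoch %d; keeping last finite checkpoint",
        stage, e
      ))
      break
    }
    gn <- sqrt(sum(g^2))
    if (gn > cfg$grad_clip) g <- g * cfg$grad_clip / gn
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^e)
    vh <- v / (1 - b2^e)
    par <- par - lr * mh / (sqrt(vh) + eps)

    cl <- clean_loss(par)
    if (is.finite(cl) && cl < best_loss) {
      best_loss <- cl
      best_par <- par
    }
    history <- rbind(history, data.frame(
      stage = stage, epoch = e, loss = cl,
      alpha = stats::plogis(par[ta_idx])
    ))
  }

  model$par <- best_par
  attr(model, "history") <- rbind(attr(model, "history"), history)
  attr(model, "stage_loss") <- best_loss
  model
}

# scenario set -> training targets (dense daily series on the trajectory)
scenario_targets <- function(scenarios, baseline_count) {
  lapply(scenarios, function(sc) {
    list(
      series = list(observations = data.frame(
        day = sc$trajectory$days, count = pmax(sc$trajectory$circ, 1e-6)
      )),
      schedule = sc$schedule,
      horizon = max(sc$trajectory$days),
      baseline_count = baseline_count
    )
  })
}

#' Pre-train a NARX model on mechanistic therapy scenarios
#'
#' The network learns to reproduce the simulated trajectories: the first
#' half of the epochs run teacher-forced on the dense daily targets, the
#' second half closed-loop, so long rollouts stay anchored. No dropout and
#' no input-noise augmentation are used (the noise augmentation is
#' reserved for stages that learn real patient data).
#'
#' @param model a [narx_model()].
#' @param scenarios a [make_scenarios()] result.
#' @param cfg a [training_config()].
#' @return The pre-trained model (epoch history in `attr(, "history")`).
#' @export
pretrain <- function(model, scenarios, cfg) {
  if (length(scenarios) == 0L) stop("scenario set is empty")
  baseline <- scenarios[[1]]$trajectory$circ[1]
  targets <- scenario_targets(scenarios, baseline)
  narx_train_stage(model, targets,
    epochs = cfg$epochs_pretrain,
    lr = cfg$learning_rate_pretrain, cfg = cfg, stage = "pretrain",
    noise_sd = 0, dropout_rate = 0, teacher_force = "mixed",
    seed = cfg$seed
  )
}

#' Recalibrate the linear output map on real patient data
#'
#' All weights except those of the linear output function (`wout`, `bout`)
#' are frozen bit-identically; Gaussian input noise is active. This
#' preserves the dynamics learned from the mechanistic model while
#' anchoring the output to the patient's real counts.
#'
#' @param model a pre-trained [narx_model()].
#' @param series a [patient_series()] with the real observations.
#' @param schedule the patient's [therapy_schedule()].
#' @param cfg a [training_config()].
#' @param horizon training horizon; defaults to the end of the last cycle.
#' @return The recalibrated model.
#' @export
recalibrate_output <- function(model, series, schedule, cfg,
                               horizon = NULL) {
  if (nrow(series$observations) == 0L) stop("series has no observations")
  if (is.null(horizon)) {
    horizon <- ceiling(max(schedule$cycle_start_days) +
      schedule$cycle_length_days)
  }
  targets <- list(list(
    series = series, schedule = schedule, horizon = horizon,
    baseline_count = series$baseline_count
  ))
  narx_train_stage(model, targets,
    epochs = cfg$epochs_recalibrate,
    lr = cfg$learning_rate_recalibrate, cfg = cfg, stage = "recalibrate",
    noise_sd = cfg$input_noise_sd, dropout_rate = 0,
    trainable = narx_output_idx(model$config),
    teacher_force = "always", seed = cfg$seed + 1L
  )
}

#' Fine-tune the whole network on real patient data
#'
#' All weights (including the smoothing factor) train at the lower
#' fine-tuning learning rate with input-noise augmentation; magnitude
#' pruning is applied once at the end of the stage.
#'
#' @inheritParams recalibrate_output
#' @return The fine-tuned (and pruned) model.
#' @export
finetune <- function(model, series, schedule, cfg, horizon = NULL) {
  if (nrow(series$observations) == 0L) stop("series has no observations")
  if (is.null(horizon)) {
    horizon <- ceiling(max(schedule$cycle_start_days) +
      schedule$cycle_length_days)
  }
  targets <- list(list(
    series = series, schedule = schedule, horizon = horizon,
    baseline_count = series$baseline_count
  ))
  model <- narx_train_stage(model, targets,
    epochs = cfg$epochs_finetune,
    lr = cfg$learning_rate_finetune, cfg = cfg, stage = "finetune",
    noise_sd = cfg$input_noise_sd, dropout_rate = 0,
    teacher_force = "always", seed = cfg$seed + 2L
  )
  prune_weights(model, cfg$pruning_fraction)
}

#' Train a NARX model on real data without transfer learning
#'
#' Single-stage training with dropout (a form of non-permanent pruning),
#' Gaussian input noise and weight decay; magnitude pruning at the end.
#'
#' @inheritParams recalibrate_output
#' @return The trained (and pruned) model.
#' @export
train_no_tl <- function(model, series, schedule, cfg, horizon = NULL) {
  if (nrow(series$observations) == 0L) stop("series has no observations")
  if (is.null(horizon)) {
    horizon <- ceiling(max(schedule$cycle_start_days) +
      schedule$cycle_length_days)
  }
  targets <- list(list(
    series = series, schedule = schedule, horizon = horizon,
    baseline_count = series$baseline_count
  ))
  model <- narx_train_stage(model, targets,
    epochs = cfg$epochs_no_tl,
    lr = cfg$learning_rate_pretrain, cfg = cfg, stage = "no_tl",
    noise_sd = cfg$input_noise_sd, dropout_rate = cfg$dropout_rate,
    teacher_force = "always", seed = cfg$seed + 3L
  )
  prune_weights(model, cfg$pruning_fraction)
}

#' Read a training configuration from a YAML or JSON file
#'
#' The file holds fields of [training_config()] (any subset; the rest use
#' defaults).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [training_config()].
#' @export
read_training_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(training_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    warning("ignoring unknown training fields: ", paste(unknown, collapse = ", "))
  }
  do.call(training_config, fields[intersect(names(fields), known)])
}

#' Write the per-epoch training log of a model as JSON lines
#'
#' One JSON object per epoch with fields `stage`, `epoch`, `loss`,
#' `alpha`, taken from the model's training history.
#'
#' @param model a trained [narx_model()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_training_log <- function(model, path) {
  hist <- attr(model, "history")
  if (is.null(hist)) stop("model has no training history")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(hist))) {
    writeLines(jsonlite::toJSON(as.list(hist[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
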