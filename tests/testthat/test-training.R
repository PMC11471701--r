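# small shared fixtures: one synthetic patient with known mechanistic truth
tl_patient <- local({
  sched <- fix_schedule("d21_plain", 3)
  truth <- friberg_params(5, 0.2, 300, 1.6)
  traj <- simulate_friberg(truth, sched, horizon = 63)
  list(sched = sched, truth = truth, traj = traj)
})

fast_cfg <- function(mode = "tl", ...) {
  args <- utils::modifyList(
    list(
      mode = mode, epochs_pretrain = 120, epochs_recalibrate = 60,
      epochs_finetune = 60, epochs_no_tl = 150
    ),
    list(...)
  )
  do.call(training_config, args)
}

test_that("the objective is SMSE plus weight and smoothness penalties", {
  cfg0 <- training_config("tl",
    weight_decay = 0,
    smoothness_penalty_weight = 0
  )
  m <- narx_model(narx_config("gru", hidden_size = 3), seed = 1)
  # track matching the observations at all days and neighbors -> SMSE 0
  ser <- patient_series("x", c(3, 7), c(200, 200))
  track <- fix_track(0:10, rep(200, 11))
  m0 <- m
  m0$par[] <- 0
  expect_equal(objective(track, ser, m0, cfg0), 0)
  # weight decay only: a single weight of 2 adds 4
  cfg_wd <- training_config("tl",
    weight_decay = 1,
    smoothness_penalty_weight = 0
  )
  m1 <- m0
  m1$par[thrombonarx:::narx_slice(m1$config, "wout")[1]] <- 2
  expect_equal(objective(track, ser, m1, cfg_wd), 4)
  # the hand-computed SMSE instance: y=2 at day 1 vs predictions (1, 2, 1)
  # on log-count scale
  ser2 <- patient_series("y", 1, exp(2))
  track2 <- fix_track(0:2, exp(c(1, 2, 1)))
  expect_equal(objective(track2, ser2, m0, cfg0), 0.6, tolerance = 1e-10)
  # alpha^2 penalty with alpha = 0.5
  cfg_sp <- training_config("tl",
    weight_decay = 0,
    smoothness_penalty_weight = 2
  )
  expect_equal(objective(track, ser, m0, cfg_sp), 2 * 0.25)
})

test_that("scenario sets contain the actual schedule and honour contracts", {
  p <- tl_patient
  sc0 <- make_scenarios(p$truth, p$sched, n_variants = 0)
  expect_length(sc0, 1)
  expect_equal(sc0[[1]]$schedule$events, p$sched$events)

  sc <- make_scenarios(p$truth, p$sched, n_variants = 7)
  expect_length(sc, 8)
  # variant 1 is the dose-0 scaling: constant at c0
  expect_lt(max(abs(sc[[2]]$trajectory$circ - p$truth$c0)) / p$truth$c0, 1e-6)
  for (s in sc) {
    expect_true(all(s$trajectory$circ > 0))
    # recovery towards baseline after the last cycle
    circ <- s$trajectory$circ
    expect_lt(
      abs(circ[length(circ)] - p$truth$c0),
      max(abs(min(circ) - p$truth$c0), 1e-6) + 1e-6
    )
  }
  # deterministic
  sc2 <- make_scenarios(p$truth, p$sched, n_variants = 7)
  expect_identical(
    lapply(sc, function(s) s$trajectory$circ),
    lapply(sc2, function(s) s$trajectory$circ)
  )
})

test_that("pretraining learns steady-state and mechanistic dynamics", {
  p <- tl_patient
  cfg <- fast_cfg()
  # steady-state-only scenarios (zero toxicity): closed loop stays near c0
  flat <- friberg_params(p$truth$mtt, p$truth$gamma, 300, 0)
  sc_flat <- make_scenarios(flat, p$sched, n_variants = 2)
  m <- narx_model(narx_config("gru"), seed = 2)
  m_flat <- pretrain(m, sc_flat, cfg)
  track <- predict_closed_loop(m_flat, 300, p$sched, 63)
  expect_lt(max(abs(track$counts - 300)) / 300, 0.10)

  # real scenarios: pretraining beats the untrained model on the actual
  # schedule trajectory
  sc <- make_scenarios(p$truth, p$sched, n_variants = 5)
  ser_actual <- patient_series(
    "actual", sc[[1]]$trajectory$days,
    pmax(sc[[1]]$trajectory$circ, 1e-6)
  )
  m0 <- narx_model(narx_config("gru"), seed = 2)
  m1 <- pretrain(m0, sc, cfg)
  untrained_smse <- smse(ser_actual, predict_closed_loop(m0, 300, p$sched, 63))
  trained_smse <- smse(ser_actual, predict_closed_loop(m1, 300, p$sched, 63))
  expect_lt(trained_smse, untrained_smse)

  # determinism and best-so-far bookkeeping
  m1b <- pretrain(narx_model(narx_config("gru"), seed = 2), sc, cfg)
  expect_identical(m1$par, m1b$par)
  hist <- attr(m1, "history")
  expect_true(all(diff(cummin(hist$loss)) <= 0))
})

test_that("recalibration only moves the linear output map", {
  p <- tl_patient
  cfg <- fast_cfg()
  sc <- make_scenarios(p$truth, p$sched, n_variants = 3)
  m <- pretrain(narx_model(narx_config("gru"), seed = 3), sc, cfg)

  set.seed(99)
  obs_days <- c(0, 8, 12, 25, 33, 47, 55)
  traj_at <- p$traj$circ[match(obs_days, p$traj$days)]
  ser <- patient_series("p", obs_days, traj_at * exp(rnorm(7, 0, 0.1)))

  m_rec <- recalibrate_output(m, ser, p$sched, cfg)
  frozen <- setdiff(
    seq_along(m$par),
    thrombonarx:::narx_output_idx(m$config)
  )
  expect_identical(m_rec$par[frozen], m$par[frozen])

  # training SMSE does not get worse
  before <- smse(ser, predict_closed_loop(m, ser$baseline_count, p$sched, 63,
    observations = ser, teacher_forcing = TRUE
  ))
  after <- smse(ser, predict_closed_loop(m_rec, ser$baseline_count, p$sched,
    63,
    observations = ser, teacher_forcing = TRUE
  ))
  expect_lte(after, before + 1e-8)

  # on data identical to the pretraining target the output map barely moves
  ser_sim <- patient_series(
    "sim", sc[[1]]$trajectory$days,
    pmax(sc[[1]]$trajectory$circ, 1e-6)
  )
  m_rec2 <- recalibrate_output(m, ser_sim, p$sched, cfg)
  oidx <- thrombonarx:::narx_output_idx(m$config)
  denom <- max(abs(m$par[oidx]), 1e-3)
  expect_lt(max(abs(m_rec2$par[oidx] - m$par[oidx])) / denom, 0.01)

  expect_error(
    recalibrate_output(
      m,
      structure(list(observations = data.frame()), class = "patient_series"),
      p$sched, cfg
    ),
    "no observations"
  )
})

test_that("fine-tuning trains everything, then prunes once", {
  p <- tl_patient
  cfg <- fast_cfg(pruning_fraction = 0.5)
  sc <- make_scenarios(p$truth, p$sched, n_variants = 3)
  m <- pretrain(narx_model(narx_config("gru", hidden_size = 6), seed = 4), sc, cfg)
  set.seed(100)
  obs_days <- c(0, 8, 12, 25, 33, 47, 55)
  traj_at <- p$traj$circ[match(obs_days, p$traj$days)]
  ser <- patient_series("p", obs_days, traj_at * exp(rnorm(7, 0, 0.1)))
  m <- recalibrate_output(m, ser, p$sched, cfg)
  m_ft <- finetune(m, ser, p$sched, cfg)
  idx <- thrombonarx:::narx_prunable(m$config)
  expect_equal(sum(m_ft$par[idx] == 0) >= ceiling(0.5 * length(idx)), TRUE)

  cfg0 <- fast_cfg(pruning_fraction = 1e-9) # effectively unpruned
  m_ft0 <- finetune(m, ser, p$sched, cfg0)
  after <- smse(ser, predict_closed_loop(m_ft0, ser$baseline_count, p$sched,
    63,
    observations = ser, teacher_forcing = TRUE
  ))
  before <- smse(ser, predict_closed_loop(m, ser$baseline_count, p$sched, 63,
    observations = ser, teacher_forcing = TRUE
  ))
  expect_lte(after, before + 1e-8)
})

test_that("noise augmentation is confined to real-data stages", {
  p <- tl_patient
  sc <- make_scenarios(p$truth, p$sched, n_variants = 2)
  cfg_a <- fast_cfg(input_noise_sd = 0)
  cfg_b <- fast_cfg(input_noise_sd = 0.3)
  # pretraining ignores the noise setting entirely
  pre_a <- pretrain(narx_model(narx_config("gru"), seed = 5), sc, cfg_a)
  pre_b <- pretrain(narx_model(narx_config("gru"), seed = 5), sc, cfg_b)
  expect_identical(pre_a$par, pre_b$par)
  # fine-tuning responds to it
  set.seed(101)
  obs_days <- c(0, 8, 12, 25, 33)
  traj_at <- p$traj$circ[match(obs_days, p$traj$days)]
  ser <- patient_series("p", obs_days, traj_at * exp(rnorm(5, 0, 0.1)))
  ft_a <- finetune(pre_a, ser, p$sched, cfg_a)
  ft_b <- finetune(pre_b, ser, p$sched, cfg_b)
  expect_false(identical(ft_a$par, ft_b$par))
})

test_that("training without transfer learning converges on rich data", {
  p <- tl_patient
  ser <- patient_series("rich", p$traj$days, pmax(p$traj$circ, 1e-6))
  cfg <- fast_cfg("no_tl", dropout_rate = 0.1, epochs_no_tl = 300)
  m0 <- narx_model(narx_config("gru"), seed = 6)
  m1 <- train_no_tl(m0, ser, p$sched, cfg)
  m1b <- train_no_tl(narx_model(narx_config("gru"), seed = 6), ser, p$sched, cfg)
  expect_identical(m1$par, m1b$par) # seeded dropout/noise -> deterministic
  init <- smse(ser, predict_closed_loop(m0, 300, p$sched, 63,
    observations = ser, teacher_forcing = TRUE
  ))
  final <- smse(ser, predict_closed_loop(m1, 300, p$sched, 63,
    observations = ser, teacher_forcing = TRUE
  ))
  expect_lt(final, init / 10)
})
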