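test_that("a zero-weight network predicts the scaled-space origin", {
  cfg <- narx_config("gru", hidden_size = 4)
  m <- narx_model(cfg, seed = 1)
  m$par[] <- 0 # all weights zero; logit(alpha) = 0 -> alpha = 0.5
  tr <- m$transform
  baseline <- inverse_scale(0, tr) # ~86.6e9, the scaled origin
  sched <- fix_schedule("d21_plain", 2)
  track <- predict_closed_loop(m, baseline, sched, horizon = 42)
  expect_equal(length(track$days), 43)
  expect_true(all(abs(track$raw) < 1e-12))
  expect_true(all(abs(track$counts - baseline) / baseline < 1e-10))
})

test_that("closed-loop prediction is deterministic and pins day zero", {
  for (arch in c("gru", "fnn")) {
    m1 <- narx_model(narx_config(arch), seed = 11)
    m2 <- narx_model(narx_config(arch), seed = 11)
    sched <- fix_schedule("d14_plain", 2)
    t1 <- predict_closed_loop(m1, 280, sched, horizon = 28)
    t2 <- predict_closed_loop(m2, 280, sched, horizon = 28)
    expect_identical(t1$counts, t2$counts)
    expect_equal(t1$counts[1], 280, tolerance = 1e-10)
    expect_identical(t1$smoothed[1], t1$raw[1])
    expect_true(all(t1$counts > 0))
    # degenerate horizon
    short <- predict_closed_loop(m1, 280, fix_schedule("d14_plain", 1), 1)
    expect_equal(length(short$counts), 2)
    expect_equal(short$counts[1], 280, tolerance = 1e-10)
  }
})

test_that("teacher-forced FNN forgets beyond its delay line, GRU does not", {
  # dense observations force the feedback everywhere, so the FNN input at
  # day t only sees the last n_delays observations plus the current dose;
  # a dose perturbation at day 10 cannot reach FNN predictions after
  # day 10 + n_delays + 1, while the GRU hidden state carries it forward
  nd <- 4
  sched_a <- therapy_schedule(
    data.frame(start_day = c(0, 10), normalized_dose = c(1, 1)), 21, 2
  )
  sched_b <- therapy_schedule(
    data.frame(start_day = c(0, 10), normalized_dose = c(1, 0.2)), 21, 2
  )
  obs <- patient_series("x", 0:35, 250 + 20 * sin(0:35 / 4))
  for (arch in c("fnn", "gru")) {
    cfg <- narx_config(arch, n_delays = nd, hidden_size = 6)
    m <- narx_model(cfg, seed = 3)
    m$par <- m$par + stats::rnorm(length(m$par), 0, 0.2)
    ta <- predict_closed_loop(m, 250, sched_a, 35,
      observations = obs, teacher_forcing = TRUE
    )
    tb <- predict_closed_loop(m, 250, sched_b, 35,
      observations = obs, teacher_forcing = TRUE
    )
    late <- (10 + nd + 2):36 # indices of days > 10 + nd + 1
    if (arch == "fnn") {
      expect_equal(ta$raw[late], tb$raw[late], tolerance = 1e-12)
    } else {
      expect_gt(max(abs(ta$raw[late] - tb$raw[late])), 1e-6)
    }
    # both react where the perturbed dose enters
    expect_gt(max(abs(ta$raw[12:16] - tb$raw[12:16])), 1e-8)
  }
})

test_that("analytic gradients match finite differences through the rollout", {
  set.seed(42)
  sched <- fix_schedule("d21_plain", 2)
  obs <- patient_series("x", c(0, 5, 10, 17, 25, 33, 40),
    c(300, 220, 140, 250, 200, 260, 310))
  for (arch in c("gru", "fnn")) {
    cfg <- narx_config(arch, hidden_size = 3, warmup_days = 2)
    m <- narx_model(cfg, seed = 7)
    m$par <- m$par + rnorm(length(m$par), 0, 0.1)
    target <- list(
      series = obs, schedule = sched, horizon = 42,
      baseline_count = 300
    )
    prep <- thrombonarx:::narx_prepare_target(m, target)
    for (tf in c(FALSE, TRUE)) {
      r <- thrombonarx:::narx_eval_prepared(m$par, m, prep,
        teacher_force = tf, want_grad = TRUE
      )
      h <- 1e-6
      fd <- vapply(seq_along(m$par), function(i) {
        up <- m$par
        up[i] <- up[i] + h
        dn <- m$par
        dn[i] <- dn[i] - h
        (thrombonarx:::narx_eval_prepared(up, m, prep, teacher_force = tf)$loss -
          thrombonarx:::narx_eval_prepared(dn, m, prep, teacher_force = tf)$loss) /
          (2 * h)
      }, numeric(1))
      expect_lt(max(abs(r$grad - fd)) / max(abs(fd)), 1e-5)
    }
  }
})

test_that("magnitude pruning zeroes exactly the smallest prunable weights", {
  cfg <- narx_config("fnn", n_delays = 3, hidden_size = 5)
  m <- narx_model(cfg, seed = 9)
  idx <- thrombonarx:::narx_prunable(cfg)
  expect_identical(prune_weights(m, 0)$par, m$par)
  for (frac in c(0.25, 0.5)) {
    pruned <- prune_weights(m, frac)
    k <- ceiling(frac * length(idx))
    # brute-force oracle: sort |w| and zero the k smallest
    expected_zero <- idx[order(abs(m$par[idx]))][seq_len(k)]
    expect_true(all(pruned$par[expected_zero] == 0))
    untouched <- setdiff(seq_along(m$par), expected_zero)
    expect_identical(pruned$par[untouched], m$par[untouched])
  }
})

test_that("model checkpoints round-trip through JSON", {
  m <- narx_model(narx_config("gru", hidden_size = 5), dose_scale = 1.5, seed = 4)
  f <- tempfile(fileext = ".json")
  save_narx_model(m, f)
  m2 <- load_narx_model(f)
  expect_equal(m2$par, m$par, tolerance = 1e-12)
  expect_equal(narx_alpha(m2), narx_alpha(m), tolerance = 1e-12)
  sched <- fix_schedule("d21_plain", 1)
  expect_equal(
    predict_closed_loop(m, 300, sched, 21)$counts,
    predict_closed_loop(m2, 300, sched, 21)$counts,
    tolerance = 1e-10
  )
  unlink(f)
})
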