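test_that("toxicity effect is the dose step scaled by eeff", {
  sched <- therapy_schedule(
    data.frame(start_day = 0, normalized_dose = 1),
    cycle_length_days = 21, n_cycles = 1
  )
  p <- friberg_params(5, 0.2, 300, 0.2)
  expect_equal(toxicity_effect(sched, p, 0.5), 0.2)
  expect_equal(toxicity_effect(sched, p, 1.5), 0)
  p0 <- friberg_params(5, 0.2, 300, 0)
  expect_equal(toxicity_effect(sched, p0, c(0, 0.5, 3)), c(0, 0, 0))
  # overlapping events sum
  sched2 <- therapy_schedule(
    data.frame(start_day = c(0, 0.5), normalized_dose = c(1, 0.5)),
    cycle_length_days = 21, n_cycles = 1
  )
  expect_equal(toxicity_effect(sched2, p, 0.75), 0.2 * 1.5)
})

test_that("zero toxicity preserves the steady state", {
  p <- friberg_params(4.2, 0.25, 280, 0)
  sched <- fix_schedule("d21_plain", 6)
  tr <- simulate_friberg(p, sched, horizon = 150)
  expect_lt(max(abs(tr$circ - 280)) / 280, 1e-6)
  # empty schedule likewise
  empty <- therapy_schedule(NULL, 21, 6)
  tr2 <- simulate_friberg(friberg_params(5, 0.2, 300, 1.5), empty,
    horizon = 60
  )
  expect_lt(max(abs(tr2$circ - 300)) / 300, 1e-6)
})

test_that("production integrator matches a fine-step reference RK4", {
  p <- friberg_params(5, 0.2, 300, 1.6)
  sched <- fix_schedule("d14_intense", 2)
  prod <- simulate_friberg(p, sched, horizon = 28)
  ref <- ref_rk4(p, sched, horizon = 28, h = 1e-3)
  expect_lt(max(abs(prod$circ - ref$circ) / ref$circ), 1e-4)
})

test_that("an adaptive multistep solver reproduces the trajectory", {
  p <- friberg_params(6, 0.3, 250, 2)
  sched <- fix_schedule("d21_plain", 2)
  k <- 4 / p$mtt
  rhs <- function(t, y, parms) {
    eff <- toxicity_effect(sched, p, t)
    fb <- (p$c0 / y[5])^p$gamma
    list(c(
      k * y[1] * (1 - eff) * fb - k * y[1],
      k * (y[1] - y[2]), k * (y[2] - y[3]), k * (y[3] - y[4]),
      k * y[4] - k * y[5]
    ))
  }
  brk <- sort(unique(c(
    seq(0, 42), sched$events$start_day,
    sched$events$start_day + sched$events$duration_days
  )))
  sol <- deSolve::lsoda(rep(p$c0, 5), brk, rhs, NULL,
    hmax = 0.1, rtol = 1e-10, atol = 1e-8
  )
  circ <- sol[match(0:42, sol[, 1]), 6]
  prod <- simulate_friberg(p, sched, horizon = 42)
  expect_lt(max(abs(prod$circ - circ) / circ), 1e-4)
})

test_that("nadir depth responds monotonically to the toxicity scale", {
  sched <- fix_schedule("d21_plain", 3)
  eeffs <- c(0.3, 0.6, 1.2, 2.4, 4.8)
  nadirs <- vapply(eeffs, function(e) {
    min(simulate_friberg(
      friberg_params(5, 0.2, 300, e), sched,
      horizon = 63
    )$circ)
  }, numeric(1))
  expect_true(all(diff(nadirs) < 0))
  # a single dose perturbs, then the feedback restores the steady state
  single <- therapy_schedule(
    data.frame(start_day = 0, normalized_dose = 1), 21, 1
  )
  tr <- simulate_friberg(friberg_params(5, 0.2, 300, 1.2), single,
    horizon = 180
  )
  expect_lt(min(tr$circ), 300)
  expect_lt(abs(tr$circ[181] - 300) / 300, 0.01)
  expect_true(all(tr$circ > 0))
})

test_that("fitting recovers known parameters from dense noise-free data", {
  set.seed(7)
  prior <- population_prior()
  sched <- fix_schedule("d21_plain", 6)
  errs <- t(vapply(1:3, function(i) {
    th <- rnorm(4, prior$log_mean, prior$log_sd)
    truth <- friberg_params(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]))
    traj <- simulate_friberg(truth, sched, horizon = 126)
    ser <- patient_series(paste0("p", i), traj$days, pmax(traj$circ, 1e-6))
    fit <- fit_friberg(ser, sched, population_prior(penalty_weight = 0),
      seed = i
    )
    abs(unlist(fit[1:4]) - unlist(truth[1:4])) / unlist(truth[1:4])
  }, numeric(4)))
  expect_lt(max(apply(errs, 2, stats::median)), 0.05)
})

test_that("the prior dominates the fit when its weight is extreme", {
  sched <- fix_schedule("d21_plain", 4)
  truth <- friberg_params(5, 0.2, 300, 1.2)
  traj <- simulate_friberg(truth, sched, horizon = 84)
  ser <- patient_series("p", traj$days, pmax(traj$circ, 1e-6))
  prior <- population_prior(
    log_mean = c(mtt = log(7), gamma = log(0.3), c0 = log(250), eeff = log(0.8)),
    penalty_weight = 1e8
  )
  fit <- fit_friberg(ser, sched, prior, n_starts = 2, seed = 1)
  expect_equal(
    log(unlist(fit[1:4])), unname(prior$log_mean),
    tolerance = 1e-2, ignore_attr = TRUE
  )
})

test_that("an untreated flat series pins the baseline parameter", {
  empty <- therapy_schedule(NULL, 21, 4)
  ser <- patient_series("p", seq(0, 60, by = 5), rep(250, 13))
  fit <- fit_friberg(ser, empty, population_prior(penalty_weight = 0),
    n_starts = 4, seed = 2
  )
  expect_equal(fit$c0, 250, tolerance = 0.01)
  expect_error(
    fit_friberg(
      structure(
        list(observations = data.frame(
          day = numeric(0),
          count = numeric(0)
        )),
        class = "patient_series"
      ),
      empty, population_prior()
    ),
    "no observations"
  )
})
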