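#' Specification of a synthetic NHL-like cohort
#'
#' Emulates the structure of a 6-cycle CHOP/CHOEP-like study population:
#' individual mechanistic parameters drawn from a log-normal population
#' prior (baseline near 300e9 cells/l), 14- or 21-day cycles, optionally
#' intensified regimens (extra doses on days 1-2 of each cycle, emulating
#' etoposide), dense (>= 5 counts/cycle) or sparse (2-4 counts/cycle)
#' measurement designs, and log-normal measurement noise.
#'
#' @param n_patients number of patients.
#' @param regimen_mix named proportions over
#'   `c("d14_plain", "d14_intense", "d21_plain", "d21_intense")`; must sum
#'   to 1.
#' @param n_cycles number of therapy cycles.
#' @param prior a [population_prior()] used as the truth distribution.
#' @param dense_fraction fraction of patients with the dense design.
#' @param sparse_counts integer range `c(min, max)` of per-cycle counts in
#'   the sparse design (2-4).
#' @param noise_sd log-scale measurement noise standard deviation.
#' @param cumulative_tox per-cycle multiplicative growth factor of the
#'   toxicity scale (1 = off); emulates patients with cumulative toxicity.
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20,
                        regimen_mix = c(
                          d14_plain = 0.25, d14_intense = 0.25,
                          d21_plain = 0.25, d21_intense = 0.25
                        ),
                        n_cycles = 6,
                        prior = population_prior(),
                        dense_fraction = 0.5,
                        sparse_counts = c(2, 4),
                        noise_sd = 0.15,
                        cumulative_tox = 1,
                        seed = 1) {
  stopifnot(
    n_patients >= 1, abs(sum(regimen_mix) - 1) < 1e-8,
    all(regimen_mix >= 0), n_cycles >= 1,
    dense_fraction >= 0, dense_fraction <= 1,
    length(sparse_counts) == 2, sparse_counts[1] >= 1,
    sparse_counts[2] >= sparse_counts[1],
    noise_sd >= 0, cumulative_tox > 0
  )
  structure(
    list(
      n_patients = as.integer(n_patients), regimen_mix = regimen_mix,
      n_cycles = as.integer(n_cycles), prior = prior,
      dense_fraction = dense_fraction,
      sparse_counts = as.integer(sparse_counts),
      noise_sd = noise_sd, cumulative_tox = cumulative_tox,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# schedule of one regimen; intensified regimens add half-dose events on
# days 1 and 2 of each cycle; cumulative toxicity grows the dose per cycle
regimen_schedule <- function(regimen, n_cycles, cumulative_tox = 1) {
  cl <- if (grepl("^d14", regimen)) 14 else 21
  intense <- grepl("intense$", regimen)
  ev <- do.call(rbind, lapply(seq_len(n_cycles), function(k) {
    start <- (k - 1) * cl
    f <- cumulative_tox^(k - 1)
    e <- data.frame(
      start_day = start, normalized_dose = 1 * f, duration_days = 1
    )
    if (intense) {
      e <- rbind(e, data.frame(
        start_day = start + 1:2, normalized_dose = 0.5 * f,
        duration_days = 1
      ))
    }
    e
  }))
  therapy_schedule(ev, cycle_length_days = cl, n_cycles = n_cycles)
}

#' Sample a synthetic patient cohort
#'
#' Per patient: draw log-normal parameters from the prior, build the
#' regimen schedule, simulate the ground-truth trajectory, sample
#' measurement days per design (dense: cycle start, two nadir-region days,
#' a recovery day and two extra random days per cycle; sparse: cycle start
#' plus 1-3 random days), and multiply the true counts by
#' `exp(N(0, noise_sd^2))`. Deterministic given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return List of synthetic patients, each with `patient_id`,
#'   `true_params`, `schedule`, `series`, `group`, `trajectory`.
#' @export
sample_cohort <- function(spec) {
  set.seed(spec$seed)
  regimens <- rep(
    names(spec$regimen_mix),
    round_largest_remainder(spec$regimen_mix * spec$n_patients)
  )
  n_dense <- round(spec$dense_fraction * spec$n_patients)
  dense <- c(
    rep(TRUE, n_dense),
    rep(FALSE, spec$n_patients - n_dense)
  )

  lapply(seq_len(spec$n_patients), function(i) {
    pid <- sprintf("S%03d", i)
    lm_ <- spec$prior$log_mean
    ls_ <- spec$prior$log_sd
    th <- stats::rnorm(4, lm_, ls_)
    pars <- friberg_params(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]))
    sched <- regimen_schedule(regimens[i], spec$n_cycles,
      cumulative_tox = spec$cumulative_tox
    )
    horizon <- spec$n_cycles * sched$cycle_length_days
    traj <- simulate_friberg(pars, sched, horizon = horizon)

    days <- sample_measurement_days(
      sched, horizon, traj,
      dense = dense[i], sparse_counts = spec$sparse_counts
    )
    truth <- traj$circ[match(days, traj$days)]
    noisy <- truth * exp(stats::rnorm(length(days), 0, spec$noise_sd))
    series <- patient_series(pid, days, noisy,
      baseline_count = noisy[days == 0][1]
    )
    list(
      patient_id = pid, true_params = pars, schedule = sched,
      series = series, group = stratify(series, sched),
      trajectory = traj
    )
  })
}

round_largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  k <- round(sum(x)) - sum(fl)
  if (k > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(k)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

# measurement-day designs; dense guarantees >= 5 counts per cycle and
# nadir-region coverage, sparse deliberately does not chase the nadir
sample_measurement_days <- function(sched, horizon, traj, dense,
                                    sparse_counts) {
  cl <- sched$cycle_length_days
  win <- cycle_windows(sched)
  days <- 0
  for (k in seq_len(nrow(win))) {
    from <- win$from[k]
    to <- min(win$to[k], horizon)
    if (to - from < 4) next
    inwin <- seq.int(ceiling(from), floor(to - 1))
    if (dense) {
      nadir_day <- inwin[which.min(traj$circ[match(inwin, traj$days)])]
      picks <- c(
        from,
        max(from + 1, min(nadir_day - 1, to - 2)), # decline into nadir
        nadir_day,
        min(to - 1, nadir_day + 4) # recovery
      )
      extra <- setdiff(inwin, picks)
      picks <- c(picks, sample(extra, min(2, length(extra))))
    } else {
      n_extra <- sample(seq(sparse_counts[1] - 1, sparse_counts[2] - 1), 1)
      extra <- setdiff(inwin, from)
      picks <- c(from, sample(extra, min(n_extra, length(extra))))
    }
    days <- c(days, picks)
  }
  sort(unique(days))
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `series.csv` (`patient_id,day,platelet_count`), `schedule.csv`
#' (`patient_id,day,normalized_dose,cycle_length`), `spec.yaml` and,
#' unless `blinded = TRUE`, `truth.json` with the true parameters per
#' patient (the blinded export is what fitting code should see).
#'
#' @param cohort a [sample_cohort()] result.
#' @param directory output directory (created if missing).
#' @param spec the generating [cohort_spec()], stored for provenance.
#' @param blinded omit `truth.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, directory, spec = NULL, blinded = FALSE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  series <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(
      patient_id = p$patient_id,
      day = p$series$observations$day,
      platelet_count = p$series$observations$count
    )
  }))
  sched <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(
      patient_id = p$patient_id,
      day = p$schedule$events$start_day,
      normalized_dose = p$schedule$events$normalized_dose,
      cycle_length = p$schedule$cycle_length_days
    )
  }))
  files <- file.path(directory, c("series.csv", "schedule.csv"))
  utils::write.csv(series, files[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(sched, files[2], row.names = FALSE, quote = FALSE)
  if (!is.null(spec)) {
    f <- file.path(directory, "spec.yaml")
    sp <- spec
    sp$prior <- list(
      log_mean = as.list(sp$prior$log_mean),
      log_sd = as.list(sp$prior$log_sd),
      penalty_weight = sp$prior$penalty_weight
    )
    yaml::write_yaml(unclass(sp), f)
    files <- c(files, f)
  }
  if (!blinded) {
    truth <- lapply(cohort, function(p) {
      c(
        unclass(p$true_params),
        list(n_cycles = p$schedule$n_cycles, group = p$group)
      )
    })
    names(truth) <- vapply(cohort, `[[`, "", "patient_id")
    f <- file.path(directory, "truth.json")
    jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a cohort directory
#'
#' Parses the CSV formats of [write_cohort()]. Unknown columns are ignored
#' with a warning; missing required columns raise an error naming the
#' column.
#'
#' @param directory cohort directory.
#' @param n_cycles cycles per schedule; taken from `spec.yaml` when
#'   present.
#' @return List of patients with `patient_id`, `schedule`, `series` and,
#'   if `truth.json` exists, `true_params` and `group`.
#' @export
read_cohort <- function(directory) {
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf(
        "%s is missing required column(s): %s", file,
        paste(miss, collapse = ", ")
      ))
    }
    extra <- setdiff(names(df), cols)
    if (length(extra)) {
      warning(sprintf(
        "%s: ignoring unknown column(s) %s", file,
        paste(extra, collapse = ", ")
      ))
    }
    df[cols]
  }
  series <- need(
    utils::read.csv(file.path(directory, "series.csv")),
    c("patient_id", "day", "platelet_count"), "series.csv"
  )
  sched <- need(
    utils::read.csv(file.path(directory, "schedule.csv")),
    c("patient_id", "day", "normalized_dose", "cycle_length"),
    "schedule.csv"
  )
  spec_file <- file.path(directory, "spec.yaml")
  n_cycles <- if (file.exists(spec_file)) {
    yaml::read_yaml(spec_file)$n_cycles
  } else {
    NULL
  }
  truth_file <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_file)) {
    jsonlite::read_json(truth_file)
  } else {
    NULL
  }

  ids <- unique(series$patient_id)
  lapply(ids, function(pid) {
    s <- series[series$patient_id == pid, ]
    sc <- sched[sched$patient_id == pid, ]
    if (nrow(sc) == 0L) stop("no schedule rows for patient ", pid)
    cl <- sc$cycle_length[1]
    nc <- if (!is.null(truth[[pid]]$n_cycles)) {
      truth[[pid]]$n_cycles
    } else if (!is.null(n_cycles)) {
      n_cycles
    } else {
      max(1, floor(max(sc$day) / cl) + 1)
    }
    schedule <- therapy_schedule(
      data.frame(
        start_day = sc$day, normalized_dose = sc$normalized_dose,
        duration_days = 1
      ),
      cycle_length_days = cl, n_cycles = nc
    )
    out <- list(
      patient_id = pid,
      schedule = schedule,
      series = patient_series(pid, s$day, s$platelet_count)
    )
    if (!is.null(truth[[pid]])) {
      tp <- truth[[pid]]
      out$true_params <- friberg_params(tp$mtt, tp$gamma, tp$c0, tp$eeff)
      out$group <- tp$group
    }
    out
  })
}
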