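#' Restrict a patient series to the first calibration cycles
#'
#' Keeps baseline observations (day <= 0) and all observations before the
#' end of cycle `c_cycles`; later observations never reach the training
#' stage (no leakage).
#'
#' @param series a [patient_series()].
#' @param schedule a [therapy_schedule()].
#' @param c_cycles number of calibration cycles.
#' @return A [patient_series()] with the sliced observations.
#' @export
series_calibration <- function(series, schedule, c_cycles) {
  win <- cycle_windows(schedule)
  stopifnot(c_cycles >= 1, c_cycles <= nrow(win))
  cutoff <- win$to[c_cycles]
  obs <- series$observations
  keep <- obs$day < cutoff
  patient_series(series$patient_id, obs$day[keep], obs$count[keep],
    baseline_count = series$baseline_count,
    transfusion_flag = series$transfusion_flag
  )
}

#' Observations in the cycles after calibration
#'
#' @inheritParams series_calibration
#' @return A [patient_series()] with the held-out observations, or `NULL`
#'   if none exist.
#' @export
series_holdout <- function(series, schedule, c_cycles) {
  win <- cycle_windows(schedule)
  cutoff <- win$to[c_cycles]
  obs <- series$observations
  keep <- obs$day >= cutoff
  if (!any(keep)) {
    return(NULL)
  }
  patient_series(series$patient_id, obs$day[keep], obs$count[keep],
    baseline_count = series$baseline_count,
    transfusion_flag = series$transfusion_flag
  )
}

#' Train an individual prediction model and forecast the remaining cycles
#'
#' Runs one cell of the experiment grid for one patient: slice the series
#' to `c_cycles` calibration cycles, train the requested learner, then
#' predict the full horizon in closed loop (teacher-forced only at
#' measured days inside the calibration window) and score the held-out
#' cycles.
#'
#' @param patient list with `series`, `schedule` (as returned by
#'   [sample_cohort()] / [read_cohort()]).
#' @param architecture `"gru"`, `"fnn"`, or `"friberg"` (the mechanistic
#'   model as predictor).
#' @param mode `"tl"` or `"no_tl"` (ignored for `"friberg"`).
#' @param c_cycles number of calibration cycles.
#' @param cfg a [training_config()].
#' @param prior a [population_prior()] for the mechanistic fit.
#' @param narx a [narx_config()]; defaults to the architecture default.
#' @param seed integer seed for this cell.
#' @return List with `model` (or fitted parameters), `track`,
#'   `smse_train`, `smse_test` (`NA` if no held-out observation),
#'   `fitted_params` (TL and friberg only).
#' @export
train_patient_model <- function(patient, architecture, mode, c_cycles,
                                cfg = training_config(mode),
                                prior = population_prior(),
                                narx = NULL, seed = 1) {
  series <- patient$series
  schedule <- patient$schedule
  train_series <- series_calibration(series, schedule, c_cycles)
  test_series <- series_holdout(series, schedule, c_cycles)
  horizon <- ceiling(max(schedule$cycle_start_days) +
    schedule$cycle_length_days)

  if (architecture == "friberg") {
    fitted <- fit_friberg(train_series, schedule, prior, seed = seed)
    traj <- simulate_friberg(fitted, schedule, horizon = horizon)
    tr <- scaling_transform("gru")
    sc <- scale_count(pmax(traj$circ, 1e-6), tr)
    track <- prediction_track(traj$days, sc, sc, tr)
    out <- list(model = fitted, fitted_params = fitted, track = track)
  } else {
    ncfg <- if (is.null(narx)) narx_config(architecture) else narx
    dose_scale <- max(schedule$events$normalized_dose, 1)
    model <- narx_model(ncfg, dose_scale = dose_scale, seed = seed)
    cfg$seed <- as.integer(seed)
    fitted <- NULL
    if (mode == "tl") {
      fitted <- fit_friberg(train_series, schedule, prior, seed = seed)
      scen <- make_scenarios(fitted, schedule, horizon = horizon)
      model <- pretrain(model, scen, cfg)
      model <- recalibrate_output(model, train_series, schedule, cfg,
        horizon = horizon
      )
      model <- finetune(model, train_series, schedule, cfg,
        horizon = horizon
      )
    } else {
      model <- train_no_tl(model, train_series, schedule, cfg,
        horizon = horizon
      )
    }
    track <- predict_closed_loop(model, train_series$baseline_count,
      schedule, horizon,
      observations = train_series, teacher_forcing = TRUE
    )
    out <- list(model = model, fitted_params = fitted, track = track)
  }
  out$smse_train <- smse(train_series, out$track)
  out$smse_test <- if (is.null(test_series)) NA_real_ else {
    smse(test_series, out$track)
  }
  out$train_series <- train_series
  out$test_series <- test_series
  out
}

#' Configuration of a full experiment run
#'
#' @param cohort a cohort (list of patients) or a directory readable by
#'   [read_cohort()].
#' @param architectures subset of `c("gru", "fnn", "friberg")`.
#' @param modes subset of `c("tl", "no_tl")`.
#' @param calibration_cycles integer vector of calibration-cycle counts.
#' @param training a [training_config()].
#' @param prior a [population_prior()].
#' @param out_dir output directory.
#' @param seed master seed; per-cell seeds are derived from it.
#' @param verbose print progress.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, architectures = c("gru", "fnn"),
                              modes = c("tl", "no_tl"),
                              calibration_cycles = 1:3,
                              training = training_config(),
                              prior = population_prior(),
                              out_dir = tempfile("thrombonarx_run_"),
                              seed = 1, verbose = FALSE) {
  stopifnot(
    all(architectures %in% c("gru", "fnn", "friberg")),
    all(modes %in% c("tl", "no_tl")),
    all(calibration_cycles >= 1)
  )
  structure(
    list(
      cohort = cohort, architectures = architectures, modes = modes,
      calibration_cycles = as.integer(calibration_cycles),
      training = training, prior = prior, out_dir = out_dir,
      seed = as.integer(seed), verbose = isTRUE(verbose)
    ),
    class = "experiment_config"
  )
}

#' Run the full experiment grid
#'
#' For every (patient, architecture, mode, calibration cycles) cell:
#' train, predict the remaining cycles, and append per-patient rows to the
#' evaluation report. Per-patient failures are logged and skipped; the run
#' errors only if more than 10 percent of cells fail. Completed cells
#' (present in an existing report at `out_dir`) are skipped, making runs
#' resumable.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a list with `report` (per-patient data frame with
#'   columns patient_id, group, architecture, mode, c, smse_train,
#'   smse_test) and `dd` (degree differences per group, c, t); both are
#'   also written to `out_dir` as CSV, with aggregate means as JSON.
#' @export
run_experiment <- function(config) {
  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report_file <- file.path(config$out_dir, "report.csv")
  done <- if (file.exists(report_file)) {
    utils::read.csv(report_file)
  } else {
    NULL
  }

  rows <- list()
  tracks <- list()
  n_fail <- 0
  n_cells <- 0
  grid <- expand.grid(
    arch = config$architectures,
    mode = config$modes, cc = config$calibration_cycles,
    stringsAsFactors = FALSE
  )
  # the mechanistic comparator has no tl/no_tl distinction; run it once
  grid <- grid[!(grid$arch == "friberg" & grid$mode != config$modes[1]), ]

  for (gi in seq_len(nrow(grid))) {
    arch <- grid$arch[gi]
    mode <- grid$mode[gi]
    cc <- grid$cc[gi]
    for (pi in seq_along(cohort)) {
      patient <- cohort[[pi]]
      n_cells <- n_cells + 1
      key <- sprintf("%s_%s_%s_c%d", patient$patient_id, arch, mode, cc)
      if (!is.null(done) &&
        any(done$patient_id == patient$patient_id & done$architecture == arch &
          done$mode == mode & done$c == cc)) {
        next
      }
      cell_seed <- (config$seed * 10000L + gi * 100L + pi) %% .Machine$integer.max
      res <- tryCatch(
        train_patient_model(patient, arch, mode, cc,
          cfg = config$training, prior = config$prior, seed = cell_seed
        ),
        error = function(e) {
          warning(sprintf("cell %s failed: %s", key, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) {
        n_fail <- n_fail + 1
        next
      }
      group <- if (!is.null(patient$group)) {
        patient$group
      } else {
        stratify(patient$series, patient$schedule)
      }
      rows[[key]] <- data.frame(
        patient_id = patient$patient_id, group = group,
        architecture = arch, mode = mode, c = cc,
        smse_train = res$smse_train, smse_test = res$smse_test
      )
      tracks[[key]] <- list(
        patient = patient, track = res$track, arch = arch,
        mode = mode, cc = cc, group = group
      )
      track_df <- data.frame(
        day = res$track$days, count = res$track$counts
      )
      utils::write.csv(track_df,
        file.path(config$out_dir, paste0("track_", key, ".csv")),
        row.names = FALSE
      )
      if (config$verbose) message("done: ", key)
    }
  }
  report <- do.call(rbind, c(list(done), unname(rows)))
  if (is.null(report)) stop("no experiment cells produced results")
  rownames(report) <- NULL
  utils::write.csv(report, report_file, row.names = FALSE)

  # degree differences per (architecture, mode, c, t, group)
  dd_rows <- list()
  for (arch in unique(report$architecture)) {
    for (mode in unique(report$mode[report$architecture == arch])) {
      for (cc in config$calibration_cycles) {
        sel <- Filter(function(x) {
          x$arch == arch && x$mode == mode && x$cc == cc
        }, tracks)
        if (!length(sel)) next
        max_t <- max(vapply(sel, function(x) {
          x$patient$schedule$n_cycles
        }, numeric(1)))
        for (t in seq.int(cc + 1, max_t)) {
          cohort_ct <- lapply(sel, function(x) {
            list(
              series = x$patient$series, track = x$track,
              schedule = x$patient$schedule
            )
          })
          r <- tryCatch(dd(cc, t, cohort_ct), error = function(e) NULL)
          if (is.null(r)) next
          dd_rows[[length(dd_rows) + 1]] <- data.frame(
            architecture = arch, mode = mode, c = cc, t = t,
            dd = r$value, n_patients = r$n_patients
          )
        }
      }
    }
  }
  dd_df <- if (length(dd_rows)) do.call(rbind, dd_rows) else NULL
  if (!is.null(dd_df)) {
    utils::write.csv(dd_df, file.path(config$out_dir, "dd.csv"),
      row.names = FALSE
    )
  }

  if (n_cells > 0 && n_fail / n_cells > 0.1) {
    stop(sprintf("%d of %d experiment cells failed", n_fail, n_cells))
  }

  agg <- stats::aggregate(
    smse_test ~ architecture + mode + c,
    data = report[!is.na(report$smse_test), ], FUN = stats::median
  )
  jsonlite::write_json(agg, file.path(config$out_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(list(report = report, dd = dd_df))
}

#' Save a NARX model checkpoint
#'
#' JSON schema (version 1): config, scaling-transform anchors, dose scale,
#' smoothing factor and the flattened weight vector.
#'
#' @param model a [narx_model()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
save_narx_model <- function(model, path) {
  obj <- list(
    schema_version = 1L,
    config = unclass(model$config),
    transform = unclass(model$transform),
    dose_scale = model$dose_scale,
    alpha = narx_alpha(model),
    par = model$par
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a NARX model checkpoint
#'
#' @param path file written by [save_narx_model()].
#' @return A [narx_model()].
#' @export
load_narx_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported checkpoint schema")
  }
  cfg <- narx_config(
    obj$config$architecture, obj$config$n_delays,
    obj$config$hidden_size, obj$config$alpha_init,
    obj$config$warmup_days
  )
  tr <- scaling_transform(
    obj$transform$architecture,
    obj$transform$lower_count, obj$transform$upper_count
  )
  model <- narx_model(cfg, transform = tr, dose_scale = obj$dose_scale)
  stopifnot(length(obj$par) == length(model$par))
  model$par <- as.numeric(obj$par)
  model
}

#' Export fitted mechanistic parameters as JSON
#'
#' @param fits named list of [friberg_params()] keyed by patient id.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_friberg_fits <- function(fits, path) {
  jsonlite::write_json(lapply(fits, unclass), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
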