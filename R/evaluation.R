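#' Observed platelet series of one patient
#'
#' @param patient_id identifier.
#' @param day observation days (real, 0-based from first treatment;
#'   negative days are pre-treatment baseline measurements).
#' @param count platelet counts, 1e9 cells/l, strictly positive.
#' @param baseline_count baseline count; defaults to the earliest
#'   observation at day <= 0, or the first observation.
#' @param transfusion_flag `TRUE` if the patient received platelet
#'   transfusions (excluded from analyses).
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, day, count, baseline_count = NULL,
                           transfusion_flag = FALSE) {
  stopifnot(length(day) == length(count))
  if (any(count <= 0) || any(!is.finite(count))) {
    stop("platelet counts must be positive and finite")
  }
  ord <- order(day)
  day <- day[ord]
  count <- count[ord]
  if (is.null(baseline_count)) {
    pre <- which(day <= 0)
    baseline_count <- if (length(pre)) count[pre[length(pre)]] else count[1]
  }
  stopifnot(baseline_count > 0)
  structure(
    list(
      patient_id = patient_id,
      observations = data.frame(day = day, count = count),
      baseline_count = baseline_count,
      transfusion_flag = isTRUE(transfusion_flag)
    ),
    class = "patient_series"
  )
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf(
    "patient_series '%s': %d observations, baseline %.4g e9/l\n",
    x$patient_id, nrow(x$observations), x$baseline_count
  ))
  invisible(x)
}

#' NCI thrombocytopenia grade of a platelet count
#'
#' Grade 0: C > 150; 1: 75 < C <= 150; 2: 50 < C <= 75; 3: 25 < C <= 50;
#' 4: C <= 25 (all in 1e9 cells/l). Boundaries belong to the higher grade.
#'
#' @param count platelet counts, 1e9 cells/l, strictly positive (vectorized).
#' @return Integer grades in 0..4.
#' @export
grade <- function(count) {
  if (any(count <= 0) || any(!is.finite(count))) {
    stop("platelet counts must be positive and finite")
  }
  ifelse(count > 150, 0L,
    ifelse(count > 75, 1L,
      ifelse(count > 50, 2L,
        ifelse(count > 25, 3L, 4L)
      )
    )
  )
}

#' Modified mean-squared error on log counts (SMSE)
#'
#' Because exact measurement times are uncertain, each observation is
#' compared not only against the prediction on its (rounded) day, but also
#' against the predictions on the adjacent days with weight 0.3:
#' \deqn{SMSE = \frac{1}{N}\Big[\sum_i (y_i-\hat y_i)^2 +
#'   0.3\,s\sum_i\big((y_i-\hat y_{i-1})^2 + (y_i-\hat y_{i+1})^2\big)\Big]}
#' with `s = 1`, on log-transformed counts (no network scaling, so models
#' are comparable). Adjacent terms falling outside the prediction horizon
#' are dropped.
#'
#' @param series a [patient_series()]; observation days are rounded to the
#'   nearest integer day.
#' @param track a [prediction_track()] (or any list with `days` and
#'   `counts` on a daily grid).
#' @return Non-negative scalar.
#' @export
smse <- function(series, track) {
  obs_day <- round(series$observations$day)
  obs_log <- log(series$observations$count)
  if (length(obs_day) == 0L) stop("series has no observations")
  pred_log <- log(track$counts)
  idx <- match(obs_day, track$days)
  if (anyNA(idx)) {
    stop(sprintf(
      "no prediction available at observation day(s) %s",
      paste(obs_day[is.na(idx)], collapse = ", ")
    ))
  }
  n_days <- length(track$days)
  total <- 0
  for (j in seq_along(idx)) {
    i <- idx[j]
    total <- total + (obs_log[j] - pred_log[i])^2
    if (i - 1 >= 1) total <- total + 0.3 * (obs_log[j] - pred_log[i - 1])^2
    if (i + 1 <= n_days) total <- total + 0.3 * (obs_log[j] - pred_log[i + 1])^2
  }
  total / length(idx)
}

#' Cycle windows of a therapy schedule
#'
#' Window `k` spans `[start_k, start_{k+1})`; the last window extends one
#' cycle length past its start.
#'
#' @param schedule a [therapy_schedule()].
#' @return Data frame with columns `cycle`, `from`, `to`.
#' @export
cycle_windows <- function(schedule) {
  starts <- schedule$cycle_start_days
  ends <- c(starts[-1], starts[length(starts)] + schedule$cycle_length_days)
  data.frame(cycle = seq_along(starts), from = starts, to = ends)
}

#' Observed nadir within a cycle window
#'
#' @param series a [patient_series()].
#' @param cycle_window numeric `c(from, to)`; observations with
#'   `from <= day < to` are considered.
#' @return List with `day` and `count` of the minimum observed count (ties
#'   broken by the earliest day), or `NULL` if the window holds no
#'   observation (the cycle is then excluded from degree comparisons).
#' @export
nadir_observed <- function(series, cycle_window) {
  obs <- series$observations
  inw <- obs$day >= cycle_window[1] & obs$day < cycle_window[2]
  if (!any(inw)) {
    return(NULL)
  }
  d <- obs$day[inw]
  cnt <- obs$count[inw]
  k <- which(cnt == min(cnt))
  k <- k[which.min(d[k])]
  list(day = d[k], count = cnt[k])
}

#' Mean absolute thrombocytopenia-degree difference at cycle nadirs
#'
#' For each patient with at least one observation in target cycle `t`, the
#' observed degree is graded from the observed nadir count of that cycle,
#' and the predicted degree from the predicted count at the observed nadir
#' day. `dd` is the mean absolute degree difference over those patients;
#' predictions must come from models calibrated on `c` cycles.
#'
#' @param c number of calibration cycles used for the underlying models.
#' @param t target cycle index (`t > c`).
#' @param cohort list of elements, each a list with `series`
#'   ([patient_series()]), `track` ([prediction_track()]) and `schedule`
#'   ([therapy_schedule()]).
#' @return An object of class `dd_result` with fields `c`, `t`, `value`,
#'   `n_patients`.
#' @export
dd <- function(c, t, cohort) {
  stopifnot(t > c)
  diffs <- numeric(0)
  for (el in cohort) {
    win <- cycle_windows(el$schedule)
    if (t > nrow(win)) next
    nad <- nadir_observed(el$series, c(win$from[t], win$to[t]))
    if (is.null(nad)) next
    day <- round(nad$day)
    i <- match(day, el$track$days)
    if (is.na(i)) next
    diffs <- c(diffs, abs(grade(nad$count) - grade(el$track$counts[i])))
  }
  if (length(diffs) == 0L) stop("no evaluable patients for cycle ", t)
  structure(
    list(c = c, t = t, value = mean(diffs), n_patients = length(diffs)),
    class = "dd_result"
  )
}

#' Eligibility of a patient for analysis
#'
#' Eligible patients have platelet data in at least four therapy cycles,
#' more than one blood count in the first cycle, and no platelet
#' transfusions.
#'
#' @param series a [patient_series()].
#' @param schedule a [therapy_schedule()].
#' @return Logical.
#' @export
eligible <- function(series, schedule) {
  if (series$transfusion_flag) {
    return(FALSE)
  }
  win <- cycle_windows(schedule)
  per_cycle <- vapply(seq_len(nrow(win)), function(k) {
    sum(series$observations$day >= win$from[k] &
      series$observations$day < win$to[k])
  }, integer(1))
  sum(per_cycle >= 1) >= 4 && per_cycle[1] >= 2
}

#' Measurement-density and cycle-length stratum of a patient
#'
#' Patients whose every covered cycle holds at least five platelet counts
#' form the dense (De) group; all others are sparse (Sp). Combined with
#' the 14- vs 21-day cycle length this yields De14/De21/Sp14/Sp21.
#'
#' @inheritParams eligible
#' @return One of `"De14"`, `"De21"`, `"Sp14"`, `"Sp21"`.
#' @export
stratify <- function(series, schedule) {
  win <- cycle_windows(schedule)
  per_cycle <- vapply(seq_len(nrow(win)), function(k) {
    sum(series$observations$day >= win$from[k] &
      series$observations$day < win$to[k])
  }, integer(1))
  covered <- per_cycle[per_cycle >= 1]
  dense <- length(covered) > 0 && all(covered >= 5)
  paste0(if (dense) "De" else "Sp", schedule$cycle_length_days)
}
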