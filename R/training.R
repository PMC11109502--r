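# Headless simulator of the two visual-perceptual-learning programs:
# session scheduling, quadrant-based stimulus placement with a weighted
# defective/intact hemifield allocation, a psychometric observer, and
# per-trial logs with weekly performance summaries.

.TASKS <- c("orientation", "rotation", "depth")

#' Training protocol configuration
#'
#' Defaults follow a 12-week home-training protocol: 64 trials x 6 blocks
#' per day (384 trials/day), 5 days a week for 12 weeks (60 sessions).
#' Each trial shows a 700 ms mid-gray blank with a beep, 150 ms of
#' simultaneous central and peripheral stimuli, then a 3000 ms response
#' window. Peripheral stimuli land in the defective hemifield with odds
#' `allocation_ratio` : 1 for the defective-field program (`NV`) and in
#' the intact hemifield with the same odds for the central-field control
#' (`NV-C`); NV uses large peripheral stimuli (10 x 10 x 0.6 deg Gabor
#' cylinders) between `nv_ecc_range` degrees of eccentricity, NV-C small
#' stimuli (0.6 deg cube) within `nvc_max_ecc` degrees of fixation.
#'
#' @param trials_per_block,blocks_per_day,days_per_week,weeks Schedule.
#' @param allocation_ratio Hemifield sampling odds (default 4.3).
#' @param pre_blank_ms,stimulus_ms,response_window_ms Trial timings.
#' @param nv_stimulus_deg,nvc_stimulus_deg Stimulus extents (deg).
#' @param nv_ecc_range NV peripheral eccentricity band (deg).
#' @param nvc_max_ecc NV-C maximum eccentricity (deg); must stay inside
#'   the NV peripheral band.
#' @return A list of class `vfd_training_config`.
#' @export
training_config <- function(trials_per_block = 64, blocks_per_day = 6,
                            days_per_week = 5, weeks = 12,
                            allocation_ratio = 4.3,
                            pre_blank_ms = 700, stimulus_ms = 150,
                            response_window_ms = 3000,
                            nv_stimulus_deg = c(10, 10, 0.6),
                            nvc_stimulus_deg = c(0.6, 0.6, 0.6),
                            nv_ecc_range = c(5, 21),
                            nvc_max_ecc = 5) {
  stopifnot(trials_per_block > 0, blocks_per_day > 0, days_per_week > 0,
            weeks > 0, allocation_ratio > 0,
            nvc_max_ecc <= nv_ecc_range[1], nv_ecc_range[1] < nv_ecc_range[2])
  structure(list(trials_per_block = trials_per_block,
                 blocks_per_day = blocks_per_day,
                 days_per_week = days_per_week, weeks = weeks,
                 allocation_ratio = allocation_ratio,
                 pre_blank_ms = pre_blank_ms, stimulus_ms = stimulus_ms,
                 response_window_ms = response_window_ms,
                 nv_stimulus_deg = nv_stimulus_deg,
                 nvc_stimulus_deg = nvc_stimulus_deg,
                 nv_ecc_range = nv_ecc_range, nvc_max_ecc = nvc_max_ecc),
            class = "vfd_training_config")
}

#' Psychometric observer
#'
#' A logistic stand-in for a patient: the probability of a correct
#' same/different response at a location with true sensitivity S is
#' `0.5 + (0.5 - lapse/2) * plogis(beta * (S - theta))`, i.e. chance at
#' deep-defect locations and `1 - lapse/2` where sensitivity is high. The
#' observer fails to respond at all with probability `lapse / 2`.
#'
#' @param sensitivity Common-frame map (`x_deg`, `y_deg`, `truth_db`) of
#'   the observer's true sensitivity.
#' @param beta Psychometric slope per dB (> 0).
#' @param theta Sensitivity (dB) at the psychometric midpoint.
#' @param lapse Lapse rate in \[0, 0.1\].
#' @return A list of class `vfd_observer`.
#' @export
observer_model <- function(sensitivity, beta = 0.5, theta = 12, lapse = 0.04) {
  stopifnot(all(c("x_deg", "y_deg", "truth_db") %in% names(sensitivity)),
            beta > 0, lapse >= 0, lapse <= 0.1)
  structure(list(sensitivity = sensitivity, beta = beta, theta = theta,
                 lapse = lapse),
            class = "vfd_observer")
}

#' Probability of a correct response at given sensitivities
#' @noRd
.p_correct <- function(obs, s) {
  0.5 + (0.5 - obs$lapse / 2) * stats::plogis(obs$beta * (s - obs$theta))
}

#' Session calendar for a training program
#'
#' @param config A [training_config()].
#' @return Data frame with one row per block: `session_idx` (1..60 by
#'   default), `week`, `block_idx`, and a `task` drawn uniformly at
#'   random per block (free task choice modeled as uniform). Uses the
#'   current RNG state.
#' @export
schedule_program <- function(config = training_config()) {
  stopifnot(inherits(config, "vfd_training_config"))
  n_sessions <- config$days_per_week * config$weeks
  out <- expand.grid(block_idx = seq_len(config$blocks_per_day),
                     session_idx = seq_len(n_sessions))[, 2:1]
  out$week <- ceiling(out$session_idx / config$days_per_week)
  out$task <- sample(.TASKS, nrow(out), replace = TRUE)
  rownames(out) <- NULL
  out[, c("session_idx", "week", "block_idx", "task")]
}

#' Sample peripheral stimulus placements
#'
#' The hemifield is drawn with odds `allocation_ratio : 1` toward the
#' defective hemifield for the `NV` program and toward the intact
#' hemifield for `NV-C`; the quadrant is uniform within the chosen
#' hemifield. NV places the stimulus center uniformly in the chosen
#' quadrant within the peripheral eccentricity band; NV-C within
#' `nvc_max_ecc` degrees of fixation. Uses the current RNG state.
#'
#' @param n Number of placements.
#' @param arm `"NV"` or `"NV-C"`.
#' @param vfd A defect classification (only `side` is used).
#' @param config A [training_config()].
#' @return Data frame: `hemifield` (`"defective"`/`"intact"`),
#'   `quadrant`, `x_deg`, `y_deg`.
#' @export
sample_placement <- function(n, arm, vfd, config = training_config()) {
  arm <- match.arg(arm, c("NV", "NV-C"))
  stopifnot(inherits(config, "vfd_training_config"), n >= 1)
  side <- match.arg(vfd$side, c("left", "right"))
  r <- config$allocation_ratio
  p_def <- if (arm == "NV") r / (r + 1) else 1 / (r + 1)
  hemifield <- ifelse(stats::runif(n) < p_def, "defective", "intact")
  hemi_side <- ifelse((hemifield == "defective") == (side == "left"),
                      "left", "right")
  upper <- stats::runif(n) < 0.5
  ecc <- if (arm == "NV") config$nv_ecc_range else c(0, config$nvc_max_ecc)
  # uniform over the quadrant disc sector between the eccentricity bounds
  rad <- sqrt(stats::runif(n, ecc[1]^2, ecc[2]^2))
  ang <- stats::runif(n, 0, pi / 2)
  x <- rad * cos(ang) * ifelse(hemi_side == "left", -1, 1)
  y <- rad * sin(ang) * ifelse(upper, 1, -1)
  data.frame(hemifield = hemifield,
             quadrant = .quadrant_of(x, y),
             x_deg = x, y_deg = y)
}

#' Snap coordinates to the nearest common-frame point
#' @noRd
.snap_to_frame <- function(x, y) {
  cf <- hvf_common_frame()
  idx <- vapply(seq_along(x), function(i)
    which.min((cf$x_deg - x[i])^2 + (cf$y_deg - y[i])^2), integer(1))
  cf[idx, , drop = FALSE]
}

#' Simulate one training trial
#'
#' Looks up the observer's sensitivity at the common-frame point nearest
#' the placement, converts it to a correct-response probability through
#' the psychometric function, and samples the response: with probability
#' `lapse / 2` no response is given (always incorrect); otherwise the
#' same/different answer is correct with the psychometric probability.
#' Response times are Uniform(300, `response_window_ms`) ms.
#'
#' @param observer A [observer_model()].
#' @param placement One-row data frame from [sample_placement()].
#' @param task One of `"orientation"`, `"rotation"`, `"depth"`.
#' @return One-row data frame: task, hemifield, quadrant, placement,
#'   `match` (ground truth), `response`, `correct`, `rt_ms`.
#' @export
run_trial <- function(observer, placement, task = "orientation") {
  log <- .run_trials(observer, placement, task)
  log
}

#' Vectorized trial core
#' @noRd
.run_trials <- function(observer, placements, task) {
  n <- nrow(placements)
  snapped <- .snap_to_frame(placements$x_deg, placements$y_deg)
  idx <- match(.loc_key(snapped$x_deg, snapped$y_deg),
               .loc_key(observer$sensitivity$x_deg, observer$sensitivity$y_deg))
  s <- observer$sensitivity$truth_db[idx]
  p <- .p_correct(observer, s)
  none <- stats::runif(n) < observer$lapse / 2
  # conditional correctness keeps the marginal P(correct) at the
  # psychometric value despite the no-response lapses
  correct <- !none & stats::runif(n) < p / (1 - observer$lapse / 2)
  match_truth <- stats::runif(n) < 0.5
  response <- ifelse(none, "none",
                     ifelse(correct == match_truth, "same", "different"))
  data.frame(task = rep_len(task, n),
             hemifield = placements$hemifield,
             quadrant = placements$quadrant,
             x_deg = placements$x_deg, y_deg = placements$y_deg,
             match = match_truth, response = response, correct = correct,
             rt_ms = ifelse(none, NA_real_, stats::runif(n, 300, 3000)))
}

#' Simulate a full training program
#'
#' Runs the complete session calendar for one observer: 60 sessions of 6
#' blocks x 64 trials by default (23,040 trials). Optionally the observer
#' skips whole sessions with probability `skip_prob` (compliance
#' modeling), and its sensitivity at trained (defective-hemifield) points
#' can grow linearly by `learning_db_per_week` dB per week.
#'
#' @param observer A [observer_model()].
#' @param arm `"NV"` or `"NV-C"`.
#' @param vfd Defect classification (side used for placement).
#' @param config A [training_config()].
#' @param seed Integer seed; the log is a deterministic function of it.
#' @param skip_prob Per-session skip probability.
#' @param learning_db_per_week Sensitivity growth at defective-hemifield
#'   points, dB/week.
#' @return A list of class `vfd_session_log`: `trials` (data frame with
#'   session/block/trial indices and the [run_trial()] fields),
#'   `sessions_completed`, `compliance` (completed / scheduled).
#' @export
run_program <- function(observer, arm, vfd, config = training_config(),
                        seed, skip_prob = 0, learning_db_per_week = 0) {
  stopifnot(inherits(observer, "vfd_observer"))
  set.seed(seed)
  cal <- schedule_program(config)
  n_sessions <- config$days_per_week * config$weeks
  skipped <- stats::runif(n_sessions) < skip_prob
  side <- match.arg(vfd$side, c("left", "right"))
  def_hemi <- region_members(region_hemifield(side))
  def_keys <- .loc_key(def_hemi$x_deg, def_hemi$y_deg)
  obs_keys <- .loc_key(observer$sensitivity$x_deg, observer$sensitivity$y_deg)
  trained <- obs_keys %in% def_keys

  out <- vector("list", nrow(cal))
  for (b in seq_len(nrow(cal))) {
    ses <- cal$session_idx[b]
    if (skipped[ses]) next
    obs_b <- observer
    obs_b$sensitivity$truth_db <- observer$sensitivity$truth_db +
      trained * learning_db_per_week * (cal$week[b] - 1)
    pl <- sample_placement(config$trials_per_block, arm, vfd, config)
    log <- .run_trials(obs_b, pl, cal$task[b])
    out[[b]] <- cbind(data.frame(session_idx = ses, week = cal$week[b],
                                 block_idx = cal$block_idx[b],
                                 trial_idx = seq_len(nrow(log))), log)
  }
  trials <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(trials) <- NULL
  completed <- sum(!skipped)
  structure(list(trials = trials, sessions_scheduled = n_sessions,
                 sessions_completed = completed,
                 compliance = completed / n_sessions),
            class = "vfd_session_log")
}

#' @export
print.vfd_session_log <- function(x, ...) {
  cat("<vfd_session_log> ", nrow(x$trials), " trials over ",
      x$sessions_completed, "/", x$sessions_scheduled,
      " sessions (compliance ", round(100 * x$compliance, 1), "%)\n", sep = "")
  invisible(x)
}

#' Weekly accuracy per task
#'
#' @param log A [run_program()] log.
#' @return Data frame `week`, `task`, `n_trials`, `accuracy` (fraction
#'   correct). Empty week/task cells are simply absent.
#' @export
performance_summary <- function(log) {
  stopifnot(inherits(log, "vfd_session_log"))
  t <- log$trials
  if (is.null(t) || nrow(t) == 0L) stop("empty session log")
  agg <- stats::aggregate(correct ~ week + task, data = t,
                          FUN = function(v) c(n = length(v), acc = mean(v)))
  data.frame(week = agg$week, task = agg$task,
             n_trials = agg$correct[, "n"], accuracy = agg$correct[, "acc"])
}

#' Association between training gains and field improvement
#'
#' Spearman rank correlation between each patient's accuracy change
#' (final minus first week, per task) and the improved area in the
#' defective hemifield.
#'
#' @param summaries Named list (by patient id) of [performance_summary()]
#'   tables.
#' @param outcomes Outcome data frame with `patient_id` and
#'   `improved_area_hemi_deg2`.
#' @param task Task whose accuracy change is correlated.
#' @return A `vfd_test_result` (Spearman), or `NULL` with a warning when
#'   the accuracy changes are degenerate.
#' @export
performance_vs_outcome <- function(summaries, outcomes, task = "orientation") {
  delta <- vapply(summaries, function(s) {
    s <- s[s$task == task, ]
    if (nrow(s) < 2L) return(NA_real_)
    s$accuracy[which.max(s$week)] - s$accuracy[which.min(s$week)]
  }, numeric(1))
  idx <- match(names(delta), outcomes$patient_id)
  area <- outcomes$improved_area_hemi_deg2[idx]
  ok <- is.finite(delta) & is.finite(area)
  if (sum(ok) < 3L) stop("need at least 3 patients with usable summaries")
  if (stats::sd(delta[ok]) == 0 || stats::sd(area[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NULL)
  }
  res <- suppressWarnings(
    stats::cor.test(delta[ok], area[ok], method = "spearman"))
  .test_result("spearman_rank_correlation", res$estimate, res$p.value, sum(ok))
}
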