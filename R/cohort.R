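# Synthetic two-arm trial cohorts: age-normative sensitivity surfaces,
# hemianopic / quadrantanopic defect templates, test-retest measurement
# noise, permuted-block randomization, programmed training effects and
# dropout. The generator provides ground truth so that every downstream
# scoring stage can be checked by parameter recovery.

#' Cohort generator configuration
#'
#' All tunable parameters of the synthetic trial. Defaults emulate the
#' structure of a completed two-arm visual-training trial: 40 vs 35
#' completers analysed, 1:1 permuted-block randomization, a defect mix of
#' 56% left-sided and ~53% hemianopias, ages ~ Normal(52, 15) truncated to
#' \[19, 80\], a per-point test-retest SD of 3 dB (half the 6 dB
#' improvement criterion, which is meant to roughly double test-to-test
#' variability), and small per-arm true-improvement models.
#'
#' @param seed Integer seed; mandatory, every draw of the generator is a
#'   deterministic function of it.
#' @param n_per_arm Named length-2 vector of patients per arm.
#' @param block_size Even permuted-block size.
#' @param vfd_left Probability a patient's defect is left-sided.
#' @param p_hemianopia Probability the defect is a hemianopia (else a
#'   quadrantanopia in a random quadrant of the affected side).
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param noise_sd_db Per-point test-retest measurement SD in dB.
#' @param norm_sd_db Normative between-subject SD in dB used to map TD
#'   values to probability categories.
#' @param effect Per-arm list: `p_improve` (probability that a
#'   defective-hemifield point truly improves), `gain_mean_db`,
#'   `gain_sd_db` (normal gain, truncated at 0).
#' @param dropout Named per-arm probability of dropping out before the
#'   follow-up exam.
#' @return A list of class `vfd_cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_per_arm = c("NV" = 40, "NV-C" = 35),
                          block_size = 4,
                          vfd_left = 0.56,
                          p_hemianopia = 0.533,
                          age_mean = 52, age_sd = 15, age_range = c(19, 80),
                          noise_sd_db = 3,
                          norm_sd_db = 3,
                          effect = list(
                            "NV" = list(p_improve = 0.115, gain_mean_db = 8, gain_sd_db = 2),
                            "NV-C" = list(p_improve = 0.105, gain_mean_db = 8, gain_sd_db = 2)),
                          dropout = c("NV" = 1 / 41, "NV-C" = 3 / 38)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            length(n_per_arm) == 2L, all(n_per_arm >= 1),
            block_size %% 2 == 0, block_size > 0,
            vfd_left >= 0, vfd_left <= 1,
            p_hemianopia >= 0, p_hemianopia <= 1,
            noise_sd_db >= 0, norm_sd_db > 0,
            all(dropout >= 0), all(dropout <= 1))
  arms <- names(n_per_arm)
  if (is.null(arms) || any(!nzchar(arms))) stop("n_per_arm must be named by arm")
  if (!setequal(names(effect), arms) || !setequal(names(dropout), arms))
    stop("effect and dropout must be named by the same arms as n_per_arm")
  structure(list(seed = as.integer(seed), n_per_arm = n_per_arm,
                 block_size = block_size, vfd_left = vfd_left,
                 p_hemianopia = p_hemianopia, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 noise_sd_db = noise_sd_db, norm_sd_db = norm_sd_db,
                 effect = effect, dropout = dropout),
            class = "vfd_cohort_config")
}

#' Age-normative sensitivity surface
#'
#' A simple parametric stand-in for a normative database: sensitivity
#' declines by 0.5 dB per eccentricity ring and by 0.1 dB per year of age
#' beyond 45, clamped to \[20, 40\] dB. Rings count outward from the
#' innermost points: ring = (max(|x|, |y|) - 3) / 6.
#'
#' @param x_deg,y_deg Location coordinates (vectors recycle).
#' @param age Age in years, in \[18, 100\].
#' @return Normative sensitivity in dB.
#' @export
normative_sensitivity <- function(x_deg, y_deg, age) {
  if (any(age < 18 | age > 100)) stop("age outside [18, 100]")
  ring <- (pmax(abs(x_deg), abs(y_deg)) - 3) / 6
  pmin(pmax(33 - 0.5 * ring - 0.1 * pmax(0, age - 45), 20), 40)
}

#' Overlay a field-defect template on a truth map
#'
#' Replaces the true sensitivity in the affected hemifield or quadrant by
#' a deep defect, Uniform(0, 8) dB, with a transition band along the
#' vertical meridian (the |x| = 3 column of the affected region) drawn
#' from Uniform(8, 18) dB. Uses the current RNG state.
#'
#' @param truth Data frame with `x_deg`, `y_deg`, `truth_db` on the
#'   common frame.
#' @param classification List with `side`, `vfd_type` and (for
#'   quadrantanopia) `quadrant`, e.g. a [classify_vfd()] result.
#' @return The truth map with affected points replaced.
#' @export
apply_vfd_template <- function(truth, classification) {
  stopifnot(all(c("x_deg", "y_deg", "truth_db") %in% names(truth)))
  side <- match.arg(classification$side, c("left", "right"))
  vfd_type <- match.arg(classification$vfd_type, c("hemianopia", "quadrantanopia"))
  region <- if (vfd_type == "hemianopia") region_hemifield(side)
            else region_quadrant(classification$quadrant)
  keys <- .loc_key(truth$x_deg, truth$y_deg)
  m <- region_members(region)
  affected <- keys %in% .loc_key(m$x_deg, m$y_deg)
  band <- affected & abs(truth$x_deg) == 3
  deep <- affected & !band
  truth$truth_db[deep] <- stats::runif(sum(deep), 0, 8)
  truth$truth_db[band] <- stats::runif(sum(band), 8, 18)
  truth
}

#' Measure one noisy monocular exam of a truth map
#'
#' Simulates one perimetry exam: per-point Gaussian test-retest noise on
#' the true sensitivity, clamped to \[0, 50\] dB. Total deviation is the
#' measured sensitivity minus the age-normative value; the TD probability
#' category is the smallest c in \{0.5, 1, 2, 5\} such that TD falls below
#' the lower c-percent normal quantile (`qnorm(c/100) * norm_sd_db`), and
#' 100 (within normal limits) otherwise. The eye-native grid is produced:
#' the two nasal extension points take their truth from the nearest
#' common-frame point and the temporal blind-spot points are absent.
#'
#' @param truth Common-frame truth map (`x_deg`, `y_deg`, `truth_db`).
#' @param age Patient age (years), for the normative surface.
#' @param eye `"OD"` or `"OS"`.
#' @param visit,patient_id Exam identifiers.
#' @param noise_sd_db Measurement SD in dB (0 gives a noise-free exam).
#' @param norm_sd_db Normative SD for the probability mapping.
#' @return An [hvf_exam()].
#' @export
measure_exam <- function(truth, age, eye, visit, patient_id,
                         noise_sd_db = 3, norm_sd_db = 3) {
  frame <- hvf_native_frame(eye)
  # nasal extension points (|x| = 27) inherit the nearest tested truth
  lookup_x <- pmin(pmax(frame$x_deg, -21), 21)
  idx <- match(.loc_key(lookup_x, frame$y_deg),
               .loc_key(truth$x_deg, truth$y_deg))
  stopifnot(!anyNA(idx))
  true_s <- truth$truth_db[idx]
  sens <- pmin(pmax(true_s + stats::rnorm(length(true_s), 0, noise_sd_db), 0), 50)
  normative <- normative_sensitivity(frame$x_deg, frame$y_deg, age)
  td <- sens - normative
  cats <- c(0.5, 1, 2, 5)
  thresholds <- stats::qnorm(cats / 100) * norm_sd_db
  cat_idx <- vapply(td, function(v) match(TRUE, v < thresholds), integer(1))
  td_prob <- ifelse(is.na(cat_idx), 100, cats[pmin(cat_idx, 4L)])
  hvf_exam(patient_id, eye, visit,
           data.frame(x_deg = frame$x_deg, y_deg = frame$y_deg,
                      sensitivity_db = sens, td_db = td,
                      td_prob_pct = td_prob))
}

#' Permuted-block randomization sequence
#'
#' 1:1 two-arm assignment balanced within consecutive blocks: each
#' complete block holds exactly half of each arm in random order; a final
#' partial block is drawn without replacement from a balanced block.
#' Uses the current RNG state.
#'
#' @param n Number of patients (>= 1).
#' @param block_size Even block size.
#' @param arms Length-2 arm labels.
#' @return Character vector of `n` arm labels.
#' @export
permuted_block_randomize <- function(n, block_size = 4, arms = c("NV", "NV-C")) {
  stopifnot(n >= 1, block_size %% 2 == 0, block_size > 0, length(arms) == 2L)
  n_blocks <- ceiling(n / block_size)
  seq <- unlist(lapply(seq_len(n_blocks), function(b)
    sample(rep(arms, block_size / 2))))
  seq[seq_len(n)]
}

#' Generate a complete synthetic trial cohort
#'
#' For each patient: an arm (permuted blocks, constrained to the
#' configured per-arm totals), an age, a defect classification and the
#' corresponding baseline truth map; a true-improvement map adding
#' arm-specific gains at random sub-normal (< 30 dB) points of the
#' defective hemifield for the follow-up visit; and noisy measured exams for both eyes at both visits
#' (both eyes share one truth map, as in homonymous defects, with
#' independent measurement noise). Dropouts omit the follow-up exams.
#'
#' @param config A [cohort_config()].
#' @return A list with `exams` (list of [hvf_exam()]), `truths` (one row
#'   per patient x common-frame location: `truth_db` at baseline and the
#'   programmed `gain_db`), `meta` (per patient: arm, age, defect side /
#'   type / quadrant, dropped), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "vfd_cohort_config"))
  set.seed(config$seed)
  arms <- names(config$n_per_arm)
  n <- sum(config$n_per_arm)
  assignment <- .quota_block_randomize(config$n_per_arm, config$block_size)
  cf <- hvf_common_frame()
  hemi_members <- list(left = region_members(region_hemifield("left")),
                       right = region_members(region_hemifield("right")))

  exams <- list()
  truth_rows <- list()
  meta_rows <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    arm <- assignment[i]
    age <- .rtruncnorm1(config$age_mean, config$age_sd, config$age_range)
    side <- if (stats::runif(1) < config$vfd_left) "left" else "right"
    vfd_type <- if (stats::runif(1) < config$p_hemianopia) "hemianopia" else "quadrantanopia"
    quadrant <- if (vfd_type == "quadrantanopia")
      paste0(sample(c("U", "L"), 1), if (side == "left") "L" else "R")
    else NA_character_

    truth <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg,
                        truth_db = normative_sensitivity(cf$x_deg, cf$y_deg, age))
    truth <- apply_vfd_template(truth,
      list(side = side, vfd_type = vfd_type, quadrant = quadrant))

    hemi <- hemi_members[[side]]
    in_hemi <- .loc_key(truth$x_deg, truth$y_deg) %in%
      .loc_key(hemi$x_deg, hemi$y_deg)
    eff <- config$effect[[arm]]
    # only sub-normal points (< 30 dB true sensitivity) can truly improve;
    # already-normal points of the affected hemifield have nothing to regain
    eligible <- in_hemi & truth$truth_db < 30
    improves <- eligible & stats::runif(nrow(truth)) < eff$p_improve
    gain <- ifelse(improves,
                   pmax(0, stats::rnorm(nrow(truth), eff$gain_mean_db, eff$gain_sd_db)),
                   0)
    post_truth <- truth
    post_truth$truth_db <- pmin(truth$truth_db + gain, 50)
    dropped <- stats::runif(1) < config$dropout[[arm]]

    for (eye in c("OD", "OS")) {
      exams[[length(exams) + 1L]] <-
        measure_exam(truth, age, eye, "baseline", pid,
                     config$noise_sd_db, config$norm_sd_db)
    }
    if (!dropped) {
      for (eye in c("OD", "OS")) {
        exams[[length(exams) + 1L]] <-
          measure_exam(post_truth, age, eye, "week12", pid,
                       config$noise_sd_db, config$norm_sd_db)
      }
    }
    truth_rows[[i]] <- data.frame(patient_id = pid, x_deg = truth$x_deg,
                                  y_deg = truth$y_deg,
                                  truth_db = truth$truth_db, gain_db = gain)
    meta_rows[[i]] <- data.frame(patient_id = pid, arm = arm, age = age,
                                 vfd_side = side, vfd_type = vfd_type,
                                 vfd_quadrant = quadrant, dropped = dropped)
  }
  list(exams = exams,
       truths = do.call(rbind, truth_rows),
       meta = do.call(rbind, meta_rows),
       config = config)
}

#' One truncated-normal draw by rejection
#' @noRd
.rtruncnorm1 <- function(mean, sd, range) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
}

#' Permuted-block sequence constrained to exact per-arm totals
#' @noRd
.quota_block_randomize <- function(n_per_arm, block_size) {
  arms <- names(n_per_arm)
  seq <- permuted_block_randomize(sum(n_per_arm), block_size, arms)
  used <- stats::setNames(c(0, 0), arms)
  for (i in seq_along(seq)) {
    a <- seq[i]
    if (used[a] >= n_per_arm[a]) a <- setdiff(arms, a)
    seq[i] <- a
    used[a] <- used[a] + 1
  }
  seq
}
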