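# Pipeline orchestration: YAML configuration and the file-level commands
# that bind cohort simulation, scoring, analysis, training simulation and
# flow reporting. Each command is deterministic given its config and seed
# and is also exposed through the bundled command-line script
# (system.file("cli", "vfdtrial.R", package = "vfdtrial")).

#' Read a pipeline configuration from YAML
#'
#' The file may hold a `cohort:` section (fields of [cohort_config()]),
#' a `training:` section ([training_config()]), and an `analysis:`
#' section (`delta_db`, `alpha_pct`, `normal_cap`). Missing sections fall
#' back to package defaults; `seed` may be supplied in the file or as the
#' `seed` argument (the argument wins).
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return List with elements `cohort`, `training`, `analysis`.
#' @export
read_pipeline_config <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  ch <- raw$cohort %||% list()
  if (!is.null(seed)) ch$seed <- seed
  if (is.null(ch$seed)) stop("a seed is required (config 'cohort: seed:' or argument)")
  if (!is.null(ch$n_per_arm)) ch$n_per_arm <- unlist(ch$n_per_arm)
  if (!is.null(ch$dropout)) ch$dropout <- unlist(ch$dropout)
  cohort <- do.call(cohort_config, ch)
  training <- do.call(training_config, raw$training %||% list())
  analysis <- utils::modifyList(
    list(delta_db = 6, alpha_pct = 5, normal_cap = 30),
    raw$analysis %||% list())
  list(cohort = cohort, training = training, analysis = analysis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort and write its files
#'
#' Writes `exams.csv` (exam schema), `truths.csv` (per-location baseline
#' truth and programmed gain) and `meta.csv` (per-patient arm, age,
#' defect, dropout) into `out_dir`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the generated cohort.
#' @export
pipeline_simulate_cohort <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  write_exams(cohort$exams, file.path(out_dir, "exams.csv"))
  utils::write.csv(cohort$truths, file.path(out_dir, "truths.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$meta, file.path(out_dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Score an exam file into per-patient outcomes
#'
#' Reads monocular exams and the per-patient metadata, integrates the two
#' eyes per visit, scores each completer, and writes the outcome CSV.
#' Patients lacking a complete pair of visits (dropouts) are excluded and
#' reported, as in a completers-only analysis.
#'
#' @param exam_csv,meta_csv Input files ([pipeline_simulate_cohort()]
#'   schema).
#' @param out_csv Output outcome CSV.
#' @param delta_db,alpha_pct,normal_cap Scoring thresholds.
#' @return Invisibly, the outcomes data frame (attribute `excluded` lists
#'   patients dropped from analysis).
#' @export
pipeline_score <- function(exam_csv, meta_csv, out_csv,
                           delta_db = 6, alpha_pct = 5, normal_cap = 30) {
  exams <- read_exams(exam_csv)
  meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  fields <- integrate_cohort(exams)
  outcomes <- score_cohort(fields, meta, delta_db = delta_db,
                           normal_cap = normal_cap, alpha_pct = alpha_pct)
  write_outcomes(outcomes, out_csv)
  invisible(outcomes)
}

#' Analyse an outcome file into a trial report
#'
#' @param outcome_csv Outcome CSV ([pipeline_score()]).
#' @param out_prefix If non-`NULL`, writes `<prefix>.json` and
#'   `<prefix>.md` renderings of the report.
#' @param arms Arm labels, (treatment, control).
#' @return Invisibly, the [analyze_trial()] report.
#' @export
pipeline_analyze <- function(outcome_csv, out_prefix = NULL,
                             arms = c("NV", "NV-C")) {
  outcomes <- read_outcomes(outcome_csv)
  report <- analyze_trial(outcomes, arms = arms)
  if (!is.null(out_prefix)) {
    writeLines(report_json(report), paste0(out_prefix, ".json"))
    writeLines(report_markdown(report), paste0(out_prefix, ".md"))
  }
  invisible(report)
}

#' Simulate a training program for one synthetic patient
#'
#' Builds a defect truth map and observer for the requested defect, runs
#' the full program, and writes the trial log CSV.
#'
#' @param arm `"NV"` or `"NV-C"`.
#' @param side,vfd_type,quadrant Defect description.
#' @param seed Integer seed.
#' @param out_csv Output CSV path (`NULL` to skip writing).
#' @param config A [training_config()].
#' @param age Age used for the normative truth map.
#' @return Invisibly, the session log.
#' @export
pipeline_simulate_training <- function(arm, side, vfd_type = "hemianopia",
                                       quadrant = NA, seed, out_csv = NULL,
                                       config = training_config(), age = 52) {
  cf <- hvf_common_frame()
  set.seed(seed)
  truth <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg,
                      truth_db = normative_sensitivity(cf$x_deg, cf$y_deg, age))
  truth <- apply_vfd_template(truth, list(side = side, vfd_type = vfd_type,
                                          quadrant = quadrant))
  obs <- observer_model(truth)
  log <- run_program(obs, arm, list(side = side), config, seed = seed)
  if (!is.null(out_csv))
    utils::write.csv(log$trials, out_csv, row.names = FALSE, quote = FALSE)
  invisible(log)
}

#' Participant-flow report
#'
#' @inheritParams flow_summary
#' @param out_json If non-`NULL`, path for a JSON rendering.
#' @return Invisibly, the [flow_summary()] list.
#' @export
pipeline_flow <- function(randomized, dropped, arms = c("NV", "NV-C"),
                          out_json = NULL) {
  fs <- flow_summary(randomized, dropped, arms)
  if (!is.null(out_json)) {
    writeLines(jsonlite::toJSON(
      list(arms = fs$arms, randomized = fs$randomized,
           completed = fs$completed, completion_pct = fs$completion_pct,
           dropout_p = fs$dropout_test$p_value),
      auto_unbox = TRUE, digits = NA, pretty = TRUE), out_json)
  }
  invisible(fs)
}
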