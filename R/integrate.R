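# Binocular integration: one field map per patient/visit taking, at each
# common-frame point, the best (maximum) sensitivity across the two eyes.

#' Integrate the two monocular exams into a binocular field
#'
#' At each of the 52 common-frame locations the integrated sensitivity is
#' the maximum over the eyes tested there. Both eyes contribute at 48
#' locations; at the four blind-spot locations (x = +/-15, y = +/-3) only
#' the fellow eye is tested and its value stands in. Total deviation and
#' the TD probability category are carried over from the eye that supplied
#' the winning sensitivity (ties go to OD), so that defect masks can be
#' drawn on the integrated map. The single-eye nasal extension points
#' (|x| = 27) are dropped.
#'
#' @param od,os `hvf_exam` objects for the right and left eye of the same
#'   patient and visit.
#' @return An [hvf_exam()] with `eye = "BIN"` whose `values` gain a
#'   `source_eye` column (`"OD"` or `"OS"`).
#' @export
integrate_exams <- function(od, os) {
  stopifnot(inherits(od, "hvf_exam"), inherits(os, "hvf_exam"))
  if (od$eye != "OD" || os$eye != "OS")
    stop("integrate_exams() expects arguments in (OD, OS) order")
  if (od$patient_id != os$patient_id)
    stop("patient mismatch: ", od$patient_id, " vs ", os$patient_id)
  if (od$visit != os$visit)
    stop("visit mismatch: ", od$visit, " vs ", os$visit)

  cf <- hvf_common_frame()
  key <- .loc_key(cf$x_deg, cf$y_deg)
  iod <- match(key, .loc_key(od$values$x_deg, od$values$y_deg))
  ios <- match(key, .loc_key(os$values$x_deg, os$values$y_deg))
  # NA index = that eye's blind spot; exactly one eye covers those points
  stopifnot(all(!is.na(iod) | !is.na(ios)))

  s_od <- od$values$sensitivity_db[iod]
  s_os <- os$values$sensitivity_db[ios]
  use_od <- ifelse(is.na(s_od), FALSE, ifelse(is.na(s_os), TRUE, s_od >= s_os))
  pick <- function(col) ifelse(use_od, od$values[[col]][iod], os$values[[col]][ios])
  values <- data.frame(
    x_deg = cf$x_deg, y_deg = cf$y_deg,
    sensitivity_db = pick("sensitivity_db"),
    td_db = pick("td_db"),
    td_prob_pct = pick("td_prob_pct"),
    source_eye = ifelse(use_od, "OD", "OS")
  )
  hvf_exam(od$patient_id, "BIN", od$visit, values)
}

#' Integrate a cohort of monocular exams
#'
#' Pairs exams by (patient, visit) and integrates each complete OD/OS
#' pair. Incomplete pairs (e.g. a dropout's missing follow-up eye) are
#' skipped with a message; duplicated (patient, visit, eye) records are an
#' error.
#'
#' @param exams List of monocular `hvf_exam` objects.
#' @return List of integrated fields (`eye = "BIN"`), one per complete
#'   pair, with an attribute `skipped`: a data frame of the (patient,
#'   visit) pairs left out.
#' @export
integrate_cohort <- function(exams) {
  stopifnot(all(vapply(exams, inherits, logical(1), "hvf_exam")))
  if (length(exams) == 0L) return(structure(list(), skipped = .no_pairs()))
  pid <- vapply(exams, `[[`, character(1), "patient_id")
  visit <- vapply(exams, `[[`, character(1), "visit")
  eye <- vapply(exams, `[[`, character(1), "eye")
  if (any(eye == "BIN")) stop("cohort must contain monocular exams only")
  if (anyDuplicated(paste(pid, visit, eye)))
    stop("duplicate (patient, visit, eye) exam records")

  key <- paste(pid, visit, sep = "\r")
  groups <- split(seq_along(exams), factor(key, levels = unique(key)))
  skipped <- .no_pairs()
  out <- list()
  for (idx in groups) {
    i_od <- idx[eye[idx] == "OD"]
    i_os <- idx[eye[idx] == "OS"]
    if (length(i_od) == 1L && length(i_os) == 1L) {
      out[[length(out) + 1L]] <- integrate_exams(exams[[i_od]], exams[[i_os]])
    } else {
      skipped <- rbind(skipped,
                       data.frame(patient_id = pid[idx[1L]], visit = visit[idx[1L]]))
    }
  }
  if (nrow(skipped))
    message("skipped ", nrow(skipped),
            " (patient, visit) pair(s) lacking both eyes")
  structure(out, skipped = skipped)
}

.no_pairs <- function() data.frame(patient_id = character(0), visit = character(0))
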