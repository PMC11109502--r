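# Monocular exams and binocular-integrated fields.
#
# An exam is one Humphrey 24-2 measurement of one eye at one visit: per test
# point, the luminance sensitivity (dB), the total deviation (TD, dB below
# the age norm), and the TD probability category (0.5, 1, 2 or 5 meaning
# "worse than that percentile of normals"; 100 meaning within normal limits).

.VISITS <- c("baseline", "week12")
.EYES <- c("OD", "OS", "BIN")
.TD_PROB_LEVELS <- c(0.5, 1, 2, 5, 100)

#' Construct a visual-field exam object
#'
#' Validates and canonicalizes one field map. Monocular exams (`eye` =
#' `"OD"`/`"OS"`) must cover exactly the 52 eye-native 24-2 locations;
#' binocular-integrated fields (`eye = "BIN"`) cover the 52 common-frame
#' locations and may carry a `source_eye` column recording, per point,
#' which eye supplied the value.
#'
#' @param patient_id Character scalar.
#' @param eye `"OD"`, `"OS"`, or `"BIN"`.
#' @param visit `"baseline"` or `"week12"`.
#' @param values Data frame with columns `x_deg`, `y_deg`,
#'   `sensitivity_db` (in \[0, 50\]; values below 0 must be floored to 0
#'   upstream), `td_db`, `td_prob_pct` (one of 0.5, 1, 2, 5, 100).
#' @return An object of class `hvf_exam`; `values` is reordered into the
#'   deterministic frame order.
#' @export
hvf_exam <- function(patient_id, eye, visit, values) {
  eye <- match.arg(eye, .EYES)
  visit <- match.arg(visit, .VISITS)
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  need <- c("x_deg", "y_deg", "sensitivity_db", "td_db", "td_prob_pct")
  if (!all(need %in% names(values)))
    stop("values must have columns: ", paste(need, collapse = ", "))

  frame <- if (eye == "BIN") hvf_common_frame() else hvf_native_frame(eye)
  have <- .loc_key(values$x_deg, values$y_deg)
  want <- .loc_key(frame$x_deg, frame$y_deg)
  if (anyDuplicated(have)) stop("duplicate locations in exam values")
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra)) {
    stop("exam locations do not match the ", eye, " frame",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = "; ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = "; ")))
  }
  if (any(values$sensitivity_db < 0 | values$sensitivity_db > 50))
    stop("sensitivity_db outside [0, 50]")
  if (!all(values$td_prob_pct %in% .TD_PROB_LEVELS))
    stop("td_prob_pct must be one of ", paste(.TD_PROB_LEVELS, collapse = ", "))

  values <- values[match(want, have), , drop = FALSE]
  rownames(values) <- NULL
  structure(list(patient_id = patient_id, eye = eye, visit = visit,
                 values = values),
            class = "hvf_exam")
}

#' @export
print.hvf_exam <- function(x, ...) {
  cat("<hvf_exam> patient ", x$patient_id, ", ", x$eye, ", ", x$visit,
      ": ", nrow(x$values), " locations, mean sensitivity ",
      round(mean(x$values$sensitivity_db), 1), " dB\n", sep = "")
  invisible(x)
}

#' Exam values at given locations
#' @noRd
.exam_at <- function(exam, locs) {
  idx <- match(.loc_key(locs$x_deg, locs$y_deg),
               .loc_key(exam$values$x_deg, exam$values$y_deg))
  exam$values[idx, , drop = FALSE]
}

# ---- CSV I/O -----------------------------------------------------------

.EXAM_COLS <- c("patient_id", "visit", "eye", "x_deg", "y_deg",
                "sensitivity_db", "td_db", "td_prob_pct")

#' Read visual-field exams from CSV
#'
#' One row per test point with columns `patient_id, visit, eye, x_deg,
#' y_deg, sensitivity_db, td_db, td_prob_pct`. Rows are validated
#' individually (grid coordinates must be odd multiples of 3, sensitivity
#' in \[0, 50\], known eye/visit codes and probability categories) and any
#' violation aborts the read with the offending row numbers; each complete
#' (patient, visit, eye) group is then assembled into an [hvf_exam()],
#' which enforces the full 52-point frame.
#'
#' @param path CSV file path.
#' @return A list of `hvf_exam` objects. An empty file yields an empty
#'   list with a warning.
#' @export
read_exams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.EXAM_COLS %in% names(df)))
    stop("exam CSV must have columns: ", paste(.EXAM_COLS, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("no exam rows in ", path)
    return(list())
  }

  bad <- character(0)
  note <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      bad <<- c(bad, paste0("row ", rows + 1L, ": ", what))  # +1 for header
  }
  is_grid <- function(v) is.finite(v) & v %% 2 != 0 & v %% 3 == 0
  note(!df$visit %in% .VISITS, "unknown visit code")
  note(!df$eye %in% .EYES, "unknown eye code")
  note(!is_grid(df$x_deg) | !is_grid(df$y_deg),
       "coordinates must be odd multiples of 3")
  note(!is.finite(df$sensitivity_db) | df$sensitivity_db < 0 | df$sensitivity_db > 50,
       "sensitivity_db outside [0, 50]")
  note(!df$td_prob_pct %in% .TD_PROB_LEVELS, "invalid td_prob_pct category")
  if (length(bad))
    stop("invalid exam rows in ", path, ":\n  ",
         paste(utils::head(bad, 20L), collapse = "\n  "),
         if (length(bad) > 20L) "\n  ..." else "")

  key <- paste(df$patient_id, df$visit, df$eye, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    cols <- c("x_deg", "y_deg", "sensitivity_db", "td_db", "td_prob_pct")
    if ("source_eye" %in% names(df)) cols <- c(cols, "source_eye")
    hvf_exam(g$patient_id[1L], g$eye[1L], g$visit[1L],
             g[, intersect(cols, names(g)), drop = FALSE])
  }) |> unname()
}

#' Write visual-field exams to CSV
#'
#' Inverse of [read_exams()]: the write -> read round trip reproduces the
#' exam objects exactly.
#'
#' @param exams A list of `hvf_exam` objects (a single exam is accepted).
#' @param path Output CSV path.
#' @export
write_exams <- function(exams, path) {
  if (inherits(exams, "hvf_exam")) exams <- list(exams)
  stopifnot(all(vapply(exams, inherits, logical(1), "hvf_exam")))
  rows <- lapply(exams, function(e) {
    cbind(data.frame(patient_id = e$patient_id, visit = e$visit, eye = e$eye),
          e$values)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(.EXAM_COLS)), .EXAM_COLS))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
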