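# Defective-field classification and per-patient outcome scoring on
# binocular-integrated fields.

#' Defect mask from a baseline field
#'
#' A location is defective when its total-deviation probability category
#' is strictly below `alpha_pct` percent, i.e. its TD falls below that
#' percentile of age-matched normals.
#'
#' @param field An integrated [hvf_exam()] (`eye = "BIN"`).
#' @param alpha_pct Probability threshold in percent; default 5 selects
#'   categories 0.5, 1 and 2 but not 5 (the inequality is strict).
#' @return A [region_mask()] of the defective locations (possibly empty).
#' @export
defect_mask <- function(field, alpha_pct = 5) {
  stopifnot(inherits(field, "hvf_exam"), field$eye == "BIN")
  v <- field$values
  region_mask(v[v$td_prob_pct < alpha_pct, c("x_deg", "y_deg"), drop = FALSE])
}

#' Classify a visual field defect from its mask
#'
#' The defect side is the hemifield holding the strict majority of mask
#' points; an exact tie cannot be lateralized and is an error. The defect
#' is called a hemianopia when both quadrants of that hemifield are each
#' occupied by at least `quadrant_frac` of their 13-point capacity;
#' otherwise it is a quadrantanopia in the dominant quadrant (ties broken
#' toward the upper quadrant).
#'
#' @param mask A nonempty [region_mask()].
#' @param quadrant_frac Minimum occupied fraction of each quadrant for a
#'   hemianopia call; default 0.25.
#' @return A list of class `vfd_classification` with elements `side`
#'   (`"left"`/`"right"`), `vfd_type` (`"hemianopia"`/`"quadrantanopia"`),
#'   `quadrant` (quadrantanopia only, else `NA`), and `defect_mask`.
#' @export
classify_vfd <- function(mask, quadrant_frac = 0.25) {
  stopifnot(inherits(mask, "vfd_region"), mask$kind == "mask")
  locs <- region_members(mask)
  if (nrow(locs) == 0L) stop("cannot classify an empty defect mask")
  n_left <- sum(locs$x_deg < 0)
  n_right <- sum(locs$x_deg > 0)
  if (n_left == n_right)
    stop("defect mask is balanced across hemifields; cannot lateralize")
  side <- if (n_left > n_right) "left" else "right"

  on_side <- locs[(locs$x_deg < 0) == (side == "left"), ]
  quads <- .quadrant_of(on_side$x_deg, on_side$y_deg)
  upper <- paste0("U", if (side == "left") "L" else "R")
  lower <- paste0("L", if (side == "left") "L" else "R")
  n_up <- sum(quads == upper)
  n_lo <- sum(quads == lower)
  cap <- 13  # points per quadrant
  if (n_up >= quadrant_frac * cap && n_lo >= quadrant_frac * cap) {
    vfd_type <- "hemianopia"
    quadrant <- NA_character_
  } else {
    vfd_type <- "quadrantanopia"
    quadrant <- if (n_up >= n_lo) upper else lower
  }
  structure(list(side = side, vfd_type = vfd_type, quadrant = quadrant,
                 defect_mask = mask),
            class = "vfd_classification")
}

#' @export
print.vfd_classification <- function(x, ...) {
  cat("<vfd_classification> ", x$side, " ", x$vfd_type,
      if (!is.na(x$quadrant)) paste0(" (", x$quadrant, ")"),
      ", mask of ", nrow(region_members(x$defect_mask)), " points\n", sep = "")
  invisible(x)
}

#' Improved visual area between two visits
#'
#' Counts region locations whose sensitivity rose by at least `delta_db`
#' dB from `pre` to `post` and converts the count to degrees squared at
#' 36 deg^2 per point. Locations already at or above the normal
#' sensitivity ceiling (`normal_cap`, default 30 dB) at baseline are not
#' counted as improvable; pass `normal_cap = NULL` to disable that
#' exclusion.
#'
#' @param pre,post Integrated fields of the same patient at baseline and
#'   follow-up.
#' @param region A [regions] object.
#' @param delta_db Improvement criterion in dB; default 6, about twice
#'   the test-to-test variability of automated perimetry.
#' @param normal_cap Baseline sensitivity (dB) at or above which a point
#'   is considered already normal, or `NULL`.
#' @return Area in deg^2 (a nonnegative multiple of 36).
#' @export
improved_area <- function(pre, post, region, delta_db = 6, normal_cap = 30) {
  stopifnot(inherits(pre, "hvf_exam"), inherits(post, "hvf_exam"),
            pre$eye == "BIN", post$eye == "BIN")
  if (pre$patient_id != post$patient_id)
    stop("patient mismatch: ", pre$patient_id, " vs ", post$patient_id)
  locs <- region_members(region)
  a <- .exam_at(pre, locs)
  b <- .exam_at(post, locs)
  gained <- (b$sensitivity_db - a$sensitivity_db) >= delta_db
  if (!is.null(normal_cap)) gained <- gained & a$sensitivity_db < normal_cap
  hvf_point_area_deg2() * sum(gained)
}

#' Mean total deviation over a region
#'
#' @param field An integrated field.
#' @param region A nonempty [regions] object.
#' @return Mean TD in dB (typically negative in a defect).
#' @export
mtd <- function(field, region) {
  stopifnot(inherits(field, "hvf_exam"), field$eye == "BIN")
  locs <- region_members(region)
  if (nrow(locs) == 0L) stop("cannot average TD over an empty region")
  mean(.exam_at(field, locs)$td_db)
}

#' Score one patient's trial outcomes
#'
#' From the baseline field: the defect mask (TD probability < `alpha_pct`)
#' and its classification. Outcomes are then computed over two regions:
#' the full 26-point hemifield on the defect side (not just the mask, so
#' that border points count) and the whole 52-point field. Per region:
#' improved area (>= `delta_db` dB sensitivity gain), mean total deviation
#' pre/post/change, and a responder flag (strictly positive MTD change).
#'
#' @param pre,post Integrated fields for the same patient at baseline and
#'   week 12.
#' @param arm Trial arm label, e.g. `"NV"` or `"NV-C"`.
#' @param delta_db,normal_cap Passed to [improved_area()].
#' @param alpha_pct Passed to [defect_mask()].
#' @return One-row data frame in the outcome schema (see
#'   [write_outcomes()]).
#' @export
score_patient <- function(pre, post, arm, delta_db = 6, normal_cap = 30,
                          alpha_pct = 5) {
  cls <- classify_vfd(defect_mask(pre, alpha_pct = alpha_pct))
  hemi <- region_hemifield(cls$side)
  whole <- region_whole()
  mtd_pre_h <- mtd(pre, hemi); mtd_post_h <- mtd(post, hemi)
  mtd_pre_w <- mtd(pre, whole); mtd_post_w <- mtd(post, whole)
  data.frame(
    patient_id = pre$patient_id,
    arm = arm,
    vfd_side = cls$side,
    vfd_type = cls$vfd_type,
    improved_area_hemi_deg2 = improved_area(pre, post, hemi, delta_db, normal_cap),
    improved_area_whole_deg2 = improved_area(pre, post, whole, delta_db, normal_cap),
    mtd_pre_hemi = mtd_pre_h,
    mtd_post_hemi = mtd_post_h,
    mtd_delta_hemi = mtd_post_h - mtd_pre_h,
    mtd_pre_whole = mtd_pre_w,
    mtd_post_whole = mtd_post_w,
    mtd_delta_whole = mtd_post_w - mtd_pre_w,
    responder_hemi = mtd_post_h - mtd_pre_h > 0,
    responder_whole = mtd_post_w - mtd_pre_w > 0
  )
}

#' Score a cohort of integrated fields
#'
#' Pairs baseline and week-12 integrated fields per patient and scores
#' each complete pair; patients missing either visit (dropouts) are
#' excluded from scoring and reported, mirroring a completers-only
#' analysis.
#'
#' @param fields List of integrated fields (both visits interleaved).
#' @param arms Named character vector or data frame (`patient_id`, `arm`)
#'   giving each patient's arm.
#' @inheritParams score_patient
#' @return Data frame of per-patient outcomes with attribute `excluded`
#'   (patient ids lacking a visit).
#' @export
score_cohort <- function(fields, arms, delta_db = 6, normal_cap = 30,
                         alpha_pct = 5) {
  stopifnot(all(vapply(fields, inherits, logical(1), "hvf_exam")))
  if (is.data.frame(arms)) arms <- stats::setNames(arms$arm, arms$patient_id)
  pid <- vapply(fields, `[[`, character(1), "patient_id")
  visit <- vapply(fields, `[[`, character(1), "visit")
  rows <- list()
  excluded <- character(0)
  for (p in unique(pid)) {
    i_pre <- which(pid == p & visit == "baseline")
    i_post <- which(pid == p & visit == "week12")
    if (length(i_pre) != 1L || length(i_post) != 1L) {
      excluded <- c(excluded, p)
      next
    }
    if (is.na(arms[p])) stop("no arm assignment for patient ", p)
    rows[[length(rows) + 1L]] <-
      score_patient(fields[[i_pre]], fields[[i_post]], unname(arms[p]),
                    delta_db, normal_cap, alpha_pct)
  }
  if (length(excluded))
    message(length(excluded), " patient(s) excluded for a missing visit: ",
            paste(excluded, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(out, excluded = excluded)
}

#' Write / read per-patient outcome tables
#'
#' @param outcomes Data frame as produced by [score_cohort()].
#' @param path CSV path.
#' @name outcome_io
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname outcome_io
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$responder_hemi <- as.logical(df$responder_hemi)
  df$responder_whole <- as.logical(df$responder_whole)
  df
}
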