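# Humphrey 24-2 test-point geometry.
#
# All coordinates are visual-field degrees: +x to the patient's right of
# fixation, +y superior. Test points sit at odd multiples of 3 degrees on a
# 6-degree lattice, so one point represents a 6 x 6 = 36 deg^2 cell.

#' Half-row of 24-2 x-coordinates for a given |y|
#' @noRd
.row_xs <- function(abs_y) {
  switch(as.character(abs_y),
    "21" = c(3, 9),
    "15" = c(3, 9, 15),
    "9"  = c(3, 9, 15, 21),
    "3"  = c(3, 9, 15, 21),
    stop("no 24-2 row at |y| = ", abs_y)
  )
}

#' Location key used for joining per-point maps
#' @noRd
.loc_key <- function(x, y) paste(x, y, sep = ",")

#' Common binocular frame of the 24-2 pattern
#'
#' The 52 test points shared by both eyes once the two single-eye nasal
#' extension points (|x| = 27) are dropped: rows at y = +/-21 span
#' x in {+/-3, +/-9}; rows at y = +/-15 add +/-15; rows at y = +/-9 and
#' y = +/-3 extend to +/-21. Each hemifield holds 26 points and each
#' quadrant 13.
#'
#' @return A data frame with columns `x_deg`, `y_deg` (52 rows), ordered
#'   row-major from superior to inferior and left to right. The order is
#'   deterministic so that files and fixtures are stable.
#' @examples
#' nrow(hvf_common_frame())  # 52
#' @export
hvf_common_frame <- function() {
  ys <- c(21, 15, 9, 3, -3, -9, -15, -21)
  rows <- lapply(ys, function(y) {
    half <- .row_xs(abs(y))
    data.frame(x_deg = sort(c(-half, half)), y_deg = y)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Eye-native 24-2 test points
#'
#' The 52 locations actually tested in one eye: the common frame plus the
#' two nasal extension points at |x| = 27, y = +/-3 on the nasal side,
#' minus the two points falling on the temporal blind spot
#' (x = +/-15, y = +/-3). For the right eye (OD) the nasal field is x < 0
#' and the blind spot at x = +15; the left eye (OS) is the mirror image.
#'
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return A data frame with columns `x_deg`, `y_deg` (52 rows) in the
#'   same deterministic ordering as [hvf_common_frame()].
#' @export
hvf_native_frame <- function(eye) {
  eye <- match.arg(eye, c("OD", "OS"))
  cf <- hvf_common_frame()
  blind_x <- if (eye == "OD") 15 else -15
  nasal_x <- if (eye == "OD") -27 else 27
  keep <- !(cf$x_deg == blind_x & abs(cf$y_deg) == 3)
  out <- rbind(cf[keep, ], data.frame(x_deg = nasal_x, y_deg = c(3, -3)))
  out <- out[order(-out$y_deg, out$x_deg), ]
  rownames(out) <- NULL
  out
}

#' Area represented by one 24-2 test point
#'
#' Points sit on a 6-degree lattice, so each represents a 6 x 6 cell:
#' 36 deg^2. Improved-area outcomes are multiples of this (2 points =
#' 72 deg^2, 3 points = 108 deg^2).
#'
#' @return 36 (deg^2).
#' @export
hvf_point_area_deg2 <- function() 36

# ---- Regions -----------------------------------------------------------

#' Scoring regions on the common binocular frame
#'
#' A region selects a subset of the 52 common-frame points over which
#' outcomes (improved area, mean total deviation) are computed: the whole
#' field, a left/right hemifield (26 points), a quadrant (13 points), or
#' an explicit mask of locations.
#'
#' @param side `"left"` or `"right"`.
#' @param quadrant One of `"UL"`, `"UR"`, `"LL"`, `"LR"` (upper/lower x
#'   left/right).
#' @param locations Data frame with columns `x_deg`, `y_deg`; must be a
#'   subset of the common frame.
#' @return An object of class `vfd_region`.
#' @name regions
NULL

.new_region <- function(kind, side = NULL, quadrant = NULL, mask = NULL) {
  structure(list(kind = kind, side = side, quadrant = quadrant, mask = mask),
            class = "vfd_region")
}

#' @rdname regions
#' @export
region_whole <- function() .new_region("whole")

#' @rdname regions
#' @export
region_hemifield <- function(side) {
  side <- match.arg(side, c("left", "right"))
  .new_region("hemifield", side = side)
}

#' @rdname regions
#' @export
region_quadrant <- function(quadrant) {
  quadrant <- match.arg(quadrant, c("UL", "UR", "LL", "LR"))
  .new_region("quadrant", quadrant = quadrant)
}

#' @rdname regions
#' @export
region_mask <- function(locations) {
  stopifnot(is.data.frame(locations),
            all(c("x_deg", "y_deg") %in% names(locations)))
  locations <- locations[, c("x_deg", "y_deg"), drop = FALSE]
  cf <- hvf_common_frame()
  bad <- !(.loc_key(locations$x_deg, locations$y_deg) %in%
             .loc_key(cf$x_deg, cf$y_deg))
  if (any(bad)) {
    stop("mask locations outside the common frame: ",
         paste(.loc_key(locations$x_deg[bad], locations$y_deg[bad]),
               collapse = "; "))
  }
  if (anyDuplicated(.loc_key(locations$x_deg, locations$y_deg)))
    stop("duplicate locations in mask")
  rownames(locations) <- NULL
  .new_region("mask", mask = locations)
}

#' @export
print.vfd_region <- function(x, ...) {
  detail <- switch(x$kind,
    whole = "",
    hemifield = paste0(" (", x$side, ")"),
    quadrant = paste0(" (", x$quadrant, ")"),
    mask = paste0(" (", nrow(x$mask), " locations)")
  )
  cat("<vfd_region> ", x$kind, detail, "\n", sep = "")
  invisible(x)
}

#' Member locations of a scoring region
#'
#' @param region A [regions] object.
#' @return Data frame of `x_deg`, `y_deg` rows drawn from the common frame.
#' @export
region_members <- function(region) {
  stopifnot(inherits(region, "vfd_region"))
  cf <- hvf_common_frame()
  out <- switch(region$kind,
    whole = cf,
    hemifield = if (region$side == "left") cf[cf$x_deg < 0, ] else cf[cf$x_deg > 0, ],
    quadrant = {
      xs <- if (region$quadrant %in% c("UL", "LL")) cf$x_deg < 0 else cf$x_deg > 0
      ys <- if (region$quadrant %in% c("UL", "UR")) cf$y_deg > 0 else cf$y_deg < 0
      cf[xs & ys, ]
    },
    mask = region$mask
  )
  rownames(out) <- NULL
  out
}

#' Quadrant label of each location
#' @noRd
.quadrant_of <- function(x, y) {
  paste0(ifelse(y > 0, "U", "L"), ifelse(x < 0, "L", "R"))
}
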