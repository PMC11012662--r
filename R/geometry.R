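# Asymmetry geometry: the six angles and four hemitrunk area ratios computed
# from one back-view landmark set. All geometry is in the y-down image pixel
# frame; angles are reported in degrees and kept at full precision (rounding
# happens only in reports).

.RAD2DEG <- 180 / pi

.geometry_stop <- function(msg) {
  stop(structure(
    class = c("trunkmetrics_geometry_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Signed tilt of a left-right landmark pair
#'
#' Angle of the vector from the patient-left point to the patient-right point
#' against the image horizontal, in degrees. Sign convention ("right-hand
#' thumb rule" viewed from the back): a clockwise tilt is positive. In the
#' y-down image frame this is `atan2(right.y - left.y, right.x - left.x)`:
#' positive exactly when the patient's right-side point sits lower in the
#' image.
#'
#' @param left,right Points `c(x, y)` with `right["x"] > left["x"]`.
#' @return Signed tilt in degrees, in (-90, 90).
#' @export
#' @examples
#' signed_tilt_deg(c(0, 0), c(10, 10)) # +45: right end lower => clockwise
signed_tilt_deg <- function(left, right) {
  dx <- right[[1L]] - left[[1L]]
  dy <- right[[2L]] - left[[2L]]
  if (dx <= 0) {
    .geometry_stop(sprintf(
      "side-order error: right.x (%g) must exceed left.x (%g)",
      right[[1L]], left[[1L]]
    ))
  }
  atan2(dy, dx) * .RAD2DEG
}

#' Shoulder, axilla and waist height angles
#'
#' Applies [signed_tilt_deg()] to the shoulder, axilla and waist pairs.
#'
#' @param lms A `back_landmarks` object.
#' @return Named numeric `c(sha_deg, aha_deg, wha_deg)`.
#' @export
height_angles <- function(lms) {
  pts <- lms$landmarks
  c(
    sha_deg = signed_tilt_deg(pts$shoulder_left, pts$shoulder_right),
    aha_deg = signed_tilt_deg(pts$axilla_left, pts$axilla_right),
    wha_deg = signed_tilt_deg(pts$waist_left, pts$waist_right)
  )
}

#' Waistline angle at the minimal-waist point
#'
#' Interior angle at the waist vertex between the ray to the same-side axilla
#' point and the ray to the same-side iliac crest point, in degrees (0, 180].
#' A straight waist crease (axilla directly above, iliac directly below)
#' gives 180; a deeper waist indentation gives a smaller angle.
#'
#' @param axilla,waist,iliac Points `c(x, y)` of one side.
#' @return Angle in degrees.
#' @export
waistline_angle <- function(axilla, waist, iliac) {
  v1 <- c(axilla[[1L]] - waist[[1L]], axilla[[2L]] - waist[[2L]])
  v2 <- c(iliac[[1L]] - waist[[1L]], iliac[[2L]] - waist[[2L]])
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    .geometry_stop("degenerate geometry: waist point coincides with axilla or iliac point")
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * .RAD2DEG
}

#' Waistline angle difference
#'
#' `lwa_deg - rwa_deg`, sign retained. A negative value means the left
#' waistline angle is the smaller (deeper left waist indentation).
#'
#' @param lwa_deg,rwa_deg Left and right waistline angles in degrees.
#' @return Signed difference in degrees.
#' @export
waistline_angle_difference <- function(lwa_deg, rwa_deg) {
  lwa_deg - rwa_deg
}

#' Shoelace polygon area
#'
#' Absolute area of a simple polygon by the shoelace formula;
#' orientation-independent.
#'
#' @param vertices Numeric matrix with 2 columns `(x, y)`, one row per vertex
#'   in boundary order (at least 3 rows), or a list of `c(x, y)` points.
#' @return Area in square pixels.
#' @export
#' @examples
#' polygon_area_px2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # 1
polygon_area_px2 <- function(vertices) {
  if (is.list(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, function(p) c(p[[1L]], p[[2L]])))
  }
  if (!is.matrix(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L) {
    .geometry_stop("polygon_area_px2 needs at least 3 (x, y) vertices")
  }
  x <- vertices[, 1L]
  y <- vertices[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Hemitrunk region areas about the C7 plumbline
#'
#' The vertical plumbline through C7 divides the trunk into left and right
#' hemitrunks; on each side three quadrilaterals are formed between the
#' plumbline and the landmark chain, bounded cranio-caudally by the
#' horizontals through that side's landmarks: the shoulder region (shoulder
#' to axilla level), the waist region (axilla to waist level) and the pelvic
#' region (waist to iliac level). Each corner on the plumbline takes the
#' same-side landmark's y, so left and right regions need not share
#' horizontal edges when the landmark heights differ. Areas are absolute
#' shoelace areas in square pixels.
#'
#' The plumbline must lie strictly between the left and right landmark of
#' every pair; otherwise a degenerate-geometry error is raised. A waist point
#' not strictly between its axilla and iliac levels gives a warning (the
#' areas are still defined).
#'
#' @param lms A `back_landmarks` object.
#' @return Object of class `hemitrunk_areas`: list with `plumbline_x` and the
#'   six areas `shoulder_left_px2`, `shoulder_right_px2`, `waist_left_px2`,
#'   `waist_right_px2`, `pelvic_left_px2`, `pelvic_right_px2`.
#' @export
hemitrunk_areas <- function(lms) {
  pts <- lms$landmarks
  px <- pts$c7[["x"]]
  for (pair in .SIDE_PAIRS) {
    l <- pts[[paste0(pair, "_left")]]
    r <- pts[[paste0(pair, "_right")]]
    if (!(l[["x"]] < px && px < r[["x"]])) {
      .geometry_stop(sprintf(
        "photo '%s': C7 plumbline (x = %g) is not strictly inside the '%s' landmark pair (%g, %g)",
        lms$photo_id, px, pair, l[["x"]], r[["x"]]
      ))
    }
  }
  region <- function(upper, lower) {
    # quadrilateral: plumbline foot at upper level, upper landmark, lower
    # landmark, plumbline foot at lower level
    polygon_area_px2(rbind(
      c(px, upper[["y"]]), c(upper[["x"]], upper[["y"]]),
      c(lower[["x"]], lower[["y"]]), c(px, lower[["y"]])
    ))
  }
  out <- list(plumbline_x = px)
  for (side in c("left", "right")) {
    sh <- pts[[paste0("shoulder_", side)]]
    ax <- pts[[paste0("axilla_", side)]]
    wa <- pts[[paste0("waist_", side)]]
    il <- pts[[paste0("iliac_", side)]]
    if (!(ax[["y"]] < wa[["y"]] && wa[["y"]] < il[["y"]])) {
      warning(sprintf(
        "photo '%s': %s waist point is not strictly between the axilla and iliac levels",
        lms$photo_id, side
      ), call. = FALSE)
    }
    out[[paste0("shoulder_", side, "_px2")]] <- region(sh, ax)
    out[[paste0("waist_", side, "_px2")]] <- region(ax, wa)
    out[[paste0("pelvic_", side, "_px2")]] <- region(wa, il)
  }
  structure(out, class = "hemitrunk_areas")
}

#' Left/right hemitrunk area ratios
#'
#' Region ratio = left area / right area for the shoulder, waist and pelvic
#' regions; the total ratio is the ratio of the summed left areas to the
#' summed right areas (so it always lies between the smallest and largest
#' region ratio — the mediant bound). A ratio of 1 means perfect left/right
#' symmetry about the C7 plumbline.
#'
#' @param areas A `hemitrunk_areas` object.
#' @return Named numeric `c(sa_ratio, wa_ratio, pa_ratio, ta_ratio)`.
#' @export
area_ratios <- function(areas) {
  left <- c(areas$shoulder_left_px2, areas$waist_left_px2, areas$pelvic_left_px2)
  right <- c(areas$shoulder_right_px2, areas$waist_right_px2, areas$pelvic_right_px2)
  regions <- c("shoulder", "waist", "pelvic")
  if (any(right == 0)) {
    .geometry_stop(sprintf(
      "undefined area ratio: zero right-side area in region(s) %s",
      paste(regions[right == 0], collapse = ", ")
    ))
  }
  c(
    sa_ratio = left[1L] / right[1L],
    wa_ratio = left[2L] / right[2L],
    pa_ratio = left[3L] / right[3L],
    ta_ratio = sum(left) / sum(right)
  )
}

#' Measure the full asymmetry profile of one photograph
#'
#' Computes the ten trunk-asymmetry parameters from one validated landmark
#' set: the signed shoulder/axilla/waist height angles (SHA, AHA, WHA;
#' clockwise-positive viewed from the back), the left and right waistline
#' angles (LWA, RWA; interior angle at the minimal-waist point between the
#' same-side axilla and iliac rays), their difference (WAD = LWA - RWA), and
#' the four left/right hemitrunk area ratios (SA, WA, PA, TA) about the C7
#' plumbline. Angles and ratios are calibration-free: the profile is
#' invariant under translation and uniform scaling of the landmarks.
#'
#' @param lms A `back_landmarks` object.
#' @param validate Run [validate_landmarks()] first (default `TRUE`).
#' @return Object of class `asymmetry_profile`: list with `photo_id`, the ten
#'   parameters (`sha_deg`, `aha_deg`, `wha_deg`, `lwa_deg`, `rwa_deg`,
#'   `wad_deg`, `sa_ratio`, `wa_ratio`, `pa_ratio`, `ta_ratio`) and the raw
#'   `areas` (`hemitrunk_areas`).
#' @seealso [profile_table()], [write_profiles()]
#' @export
measure_profile <- function(lms, validate = TRUE) {
  if (validate) validate_landmarks(lms)
  pts <- lms$landmarks
  ha <- height_angles(lms)
  lwa <- waistline_angle(pts$axilla_left, pts$waist_left, pts$iliac_left)
  rwa <- waistline_angle(pts$axilla_right, pts$waist_right, pts$iliac_right)
  areas <- hemitrunk_areas(lms)
  ratios <- area_ratios(areas)
  structure(
    list(
      photo_id = lms$photo_id,
      sha_deg = ha[["sha_deg"]],
      aha_deg = ha[["aha_deg"]],
      wha_deg = ha[["wha_deg"]],
      lwa_deg = lwa,
      rwa_deg = rwa,
      wad_deg = waistline_angle_difference(lwa, rwa),
      sa_ratio = ratios[["sa_ratio"]],
      wa_ratio = ratios[["wa_ratio"]],
      pa_ratio = ratios[["pa_ratio"]],
      ta_ratio = ratios[["ta_ratio"]],
      areas = areas
    ),
    class = "asymmetry_profile"
  )
}

#' Canonical order of the ten asymmetry parameter names
#'
#' @format Character vector: SHA, AHA, WHA, LWA, RWA, WAD, SA, WA, PA, TA.
#' @export
MEASURE_NAMES <- c("SHA", "AHA", "WHA", "LWA", "RWA", "WAD",
                   "SA", "WA", "PA", "TA")

#' Extract the ten parameters of a profile as a named vector
#'
#' @param profile An `asymmetry_profile`.
#' @return Named numeric vector in [MEASURE_NAMES] order (angles in degrees,
#'   areas as left/right ratios).
#' @export
profile_values <- function(profile) {
  stats::setNames(
    c(profile$sha_deg, profile$aha_deg, profile$wha_deg,
      profile$lwa_deg, profile$rwa_deg, profile$wad_deg,
      profile$sa_ratio, profile$wa_ratio, profile$pa_ratio, profile$ta_ratio),
    MEASURE_NAMES
  )
}

#' @export
print.asymmetry_profile <- function(x, digits = 2, ...) {
  cat(sprintf("Asymmetry profile for photo '%s'\n", x$photo_id))
  cat("  height angles (deg, clockwise positive):",
      sprintf("SHA %+.*f  AHA %+.*f  WHA %+.*f",
              digits, x$sha_deg, digits, x$aha_deg, digits, x$wha_deg), "\n")
  cat("  waistline angles (deg):",
      sprintf("LWA %.*f  RWA %.*f  WAD %+.*f",
              digits, x$lwa_deg, digits, x$rwa_deg, digits, x$wad_deg), "\n")
  cat("  left/right area ratios:",
      sprintf("SA %.*f  WA %.*f  PA %.*f  TA %.*f",
              digits, x$sa_ratio, digits, x$wa_ratio,
              digits, x$pa_ratio, digits, x$ta_ratio), "\n")
  invisible(x)
}

#' @export
as.data.frame.asymmetry_profile <- function(x, ...) {
  profile_table(list(x))
}

#' Tabulate a list of profiles
#'
#' One row per photograph: `photo_id`, the ten parameters in [MEASURE_NAMES]
#' order, the six raw region areas in square pixels, and the plumbline x.
#'
#' @param profiles List of `asymmetry_profile` objects.
#' @return A `data.frame`.
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    a <- p$areas
    data.frame(
      photo_id = p$photo_id,
      SHA = p$sha_deg, AHA = p$aha_deg, WHA = p$wha_deg,
      LWA = p$lwa_deg, RWA = p$rwa_deg, WAD = p$wad_deg,
      SA = p$sa_ratio, WA = p$wa_ratio, PA = p$pa_ratio, TA = p$ta_ratio,
      shoulder_left_px2 = a$shoulder_left_px2,
      shoulder_right_px2 = a$shoulder_right_px2,
      waist_left_px2 = a$waist_left_px2,
      waist_right_px2 = a$waist_right_px2,
      pelvic_left_px2 = a$pelvic_left_px2,
      pelvic_right_px2 = a$pelvic_right_px2,
      plumbline_x = a$plumbline_x,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a profile table to CSV
#'
#' The first line is a `#` comment documenting the units (angles in degrees,
#' clockwise positive viewed from the back; SA/WA/PA/TA as left/right area
#' ratios; raw areas in square pixels).
#'
#' @param profiles List of `asymmetry_profile` objects (or a data.frame from
#'   [profile_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(
    "# angles SHA/AHA/WHA/LWA/RWA/WAD in degrees (height angles clockwise-positive",
    "viewed from the back); SA/WA/PA/TA are left/right hemitrunk area ratios;",
    "*_px2 raw areas in square pixels"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a profile table written by [write_profiles()]
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_profiles <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
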