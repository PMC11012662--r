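# Landmark data model and validation.
#
# Coordinate convention used throughout the package: raster image pixel frame,
# origin at the top-left corner, x increasing rightward, y increasing DOWNWARD.
# Side labels are patient-anatomical; on a back-view photograph the patient's
# left appears on the image left, so left.x < right.x for every pair.

#' Names of the nine back-view anatomical landmarks
#'
#' In tagging order: the two shoulder points (acromion endpoints), the two
#' axilla points (most superior points of the posterior axillary folds), the
#' two minimal-waist points, the two iliac crest points (most external points),
#' and the C7 spinous process.
#'
#' @format Character vector of length 9.
#' @export
LANDMARK_NAMES <- c(
  "shoulder_left", "shoulder_right",
  "axilla_left", "axilla_right",
  "waist_left", "waist_right",
  "iliac_left", "iliac_right",
  "c7"
)

.SIDE_PAIRS <- c("shoulder", "axilla", "waist", "iliac")

#' Create a pixel point
#'
#' A point in image pixel coordinates: `x` is the column (increases rightward),
#' `y` the row (increases downward). Both must be finite.
#'
#' @param x,y Finite numeric scalars.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
#' @examples
#' pixel_point(120.5, 340)
pixel_point <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L) {
    stop("pixel_point: x and y must be numeric scalars", call. = FALSE)
  }
  if (!is.finite(x) || !is.finite(y)) {
    stop("pixel_point: coordinates must be finite", call. = FALSE)
  }
  c(x = as.numeric(x), y = as.numeric(y))
}

#' Create a back-view landmark set
#'
#' Bundles the nine anatomical landmarks of one back-view photograph with its
#' identifier and (optionally) the image dimensions. Validation enforces the
#' side convention (patient's left on the image left, so `left.x < right.x`
#' for every shoulder/axilla/waist/iliac pair) as a hard error; vertical
#' ordering anomalies are soft warnings reported by [check_quality()].
#'
#' @param photo_id Character identifier of the photograph.
#' @param points Named list of the 9 landmarks (names as in [LANDMARK_NAMES]),
#'   each a length-2 numeric `c(x, y)` (see [pixel_point()]).
#' @param image_width,image_height Optional image dimensions in pixels
#'   (`NA` when unknown).
#' @param validate If `TRUE` (default), run [validate_landmarks()].
#' @return Object of class `back_landmarks`.
#' @seealso [validate_landmarks()], [check_quality()], [measure_profile()]
#' @export
back_landmarks <- function(photo_id, points, image_width = NA,
                           image_height = NA, validate = TRUE) {
  if (length(photo_id) != 1L) {
    stop("photo_id must be a single identifier", call. = FALSE)
  }
  pts <- lapply(points, function(p) {
    p <- unname(as.numeric(p))
    if (length(p) != 2L) stop("each landmark must be an (x, y) pair", call. = FALSE)
    c(x = p[1L], y = p[2L])
  })
  obj <- structure(
    list(
      photo_id = as.character(photo_id),
      image_width = if (is.null(image_width)) NA_real_ else as.numeric(image_width),
      image_height = if (is.null(image_height)) NA_real_ else as.numeric(image_height),
      landmarks = pts
    ),
    class = "back_landmarks"
  )
  if (validate) validate_landmarks(obj)
  obj
}

#' Validate a landmark set (hard rules)
#'
#' Hard rules, each raising a classed error (`trunkmetrics_validation_error`):
#' all 9 landmarks present, all coordinates finite numerics, and for every
#' left/right pair `left.x < right.x` (side inversion otherwise). Soft rules
#' (vertical ordering, C7 position, image resolution) never raise; they are
#' reported by [check_quality()].
#'
#' @param lms A `back_landmarks` object (or bare list with the same fields).
#' @return The validated object, invisibly.
#' @export
validate_landmarks <- function(lms) {
  pts <- lms$landmarks
  id <- lms$photo_id
  missing <- setdiff(LANDMARK_NAMES, names(pts))
  if (length(missing) > 0L) {
    .validation_stop(sprintf(
      "photo '%s': missing landmark(s): %s", id, paste(missing, collapse = ", ")
    ))
  }
  for (nm in LANDMARK_NAMES) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p))) {
      .validation_stop(sprintf(
        "photo '%s': landmark '%s' has non-finite or malformed coordinates", id, nm
      ))
    }
  }
  for (pair in .SIDE_PAIRS) {
    l <- pts[[paste0(pair, "_left")]]
    r <- pts[[paste0(pair, "_right")]]
    if (l[["x"]] >= r[["x"]]) {
      .validation_stop(sprintf(
        "photo '%s': side inversion at '%s' pair (left.x = %g >= right.x = %g); side labels are patient-anatomical and the patient's left must be on the image left",
        id, pair, l[["x"]], r[["x"]]
      ))
    }
  }
  invisible(lms)
}

.validation_stop <- function(msg) {
  stop(structure(
    class = c("trunkmetrics_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Soft (advisory) structural warnings: coded strings, never errors.
.landmark_soft_warnings <- function(lms) {
  pts <- lms$landmarks
  codes <- character(0)
  for (side in c("left", "right")) {
    ys <- vapply(
      paste0(c("shoulder", "axilla", "waist", "iliac"), "_", side),
      function(nm) pts[[nm]][["y"]], numeric(1)
    )
    if (is.unsorted(ys)) {
      codes <- c(codes, paste0("vertical_order_", side))
    }
  }
  ax_min_y <- min(pts$axilla_left[["y"]], pts$axilla_right[["y"]])
  if (pts$c7[["y"]] > ax_min_y) codes <- c(codes, "c7_below_axillae")
  codes
}

#' Structural quality check for a landmark set
#'
#' Reports (never raises) the structural quality of a landmark annotation.
#' `passed` is `FALSE` only when a hard rule fails (missing point, non-finite
#' coordinate, left/right side inversion). Soft rules give coded warnings:
#' `vertical_order_left`/`vertical_order_right` when the
#' shoulder-axilla-waist-iliac top-to-bottom order is violated on a side,
#' `c7_below_axillae` when C7 is tagged below an axilla, and `low_resolution`
#' when the image's short side (if dimensions were recorded) is below
#' `min_short_side`.
#'
#' @param lms A `back_landmarks` object.
#' @param min_short_side Minimum acceptable short image side in pixels
#'   (default 200); only used when image dimensions are present.
#' @return Object of class `quality_report`: list with `passed` (logical) and
#'   `warnings` (character vector of codes).
#' @export
check_quality <- function(lms, min_short_side = 200) {
  hard <- tryCatch({
    validate_landmarks(lms)
    NULL
  }, trunkmetrics_validation_error = function(e) conditionMessage(e))
  if (!is.null(hard)) {
    return(structure(list(passed = FALSE, warnings = hard),
                     class = "quality_report"))
  }
  codes <- .landmark_soft_warnings(lms)
  dims <- c(lms$image_width, lms$image_height)
  if (all(is.finite(dims)) && min(dims) < min_short_side) {
    codes <- c(codes, "low_resolution")
  }
  structure(list(passed = TRUE, warnings = codes), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Quality check: %s\n", if (x$passed) "PASSED" else "FAILED"))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.back_landmarks <- function(x, ...) {
  cat(sprintf("Back-view landmarks for photo '%s'", x$photo_id))
  if (is.finite(x$image_width) && is.finite(x$image_height)) {
    cat(sprintf(" (%g x %g px image)", x$image_width, x$image_height))
  }
  cat("\n")
  m <- do.call(rbind, x$landmarks)
  rownames(m) <- names(x$landmarks)
  print(round(m, 2))
  invisible(x)
}

#' Translate a landmark set
#'
#' Adds `(dx, dy)` to every landmark. All ten asymmetry parameters are
#' invariant under translation.
#'
#' @param lms A `back_landmarks` object.
#' @param dx,dy Pixel offsets.
#' @return Translated `back_landmarks`.
#' @export
translate_landmarks <- function(lms, dx = 0, dy = 0) {
  lms$landmarks <- lapply(lms$landmarks, function(p) {
    c(x = p[["x"]] + dx, y = p[["y"]] + dy)
  })
  lms
}

#' Scale a landmark set about a center
#'
#' Uniformly scales every landmark about `center` by `factor` (> 0). Angles
#' and area ratios are dimensionless, so the asymmetry profile is invariant.
#'
#' @param lms A `back_landmarks` object.
#' @param factor Positive scale factor.
#' @param center Length-2 numeric `(x, y)`; default the C7 landmark.
#' @return Scaled `back_landmarks`.
#' @export
scale_landmarks <- function(lms, factor, center = lms$landmarks$c7) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  cx <- center[[1L]]
  cy <- center[[2L]]
  lms$landmarks <- lapply(lms$landmarks, function(p) {
    c(x = cx + factor * (p[["x"]] - cx), y = cy + factor * (p[["y"]] - cy))
  })
  lms
}

#' Mirror a landmark set about the C7 plumbline
#'
#' Reflects every landmark about the vertical line through C7 and swaps the
#' left/right labels so the result is again a valid back-view set. Under this
#' operation the signed height angles and the waistline angle difference
#' negate, the left and right waistline angles swap, and every area ratio
#' inverts.
#'
#' @param lms A `back_landmarks` object.
#' @return Mirrored `back_landmarks`.
#' @export
mirror_landmarks <- function(lms) {
  cx <- lms$landmarks$c7[["x"]]
  refl <- lapply(lms$landmarks, function(p) c(x = 2 * cx - p[["x"]], y = p[["y"]]))
  out <- refl
  for (pair in .SIDE_PAIRS) {
    out[[paste0(pair, "_left")]] <- refl[[paste0(pair, "_right")]]
    out[[paste0(pair, "_right")]] <- refl[[paste0(pair, "_left")]]
  }
  lms$landmarks <- out
  lms
}
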