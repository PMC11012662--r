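# File I/O for landmark sets: JSON and CSV, exact round trip at double
# precision (coordinates serialised with 17 significant digits).

.guess_format <- function(path, format) {
  format <- match.arg(format, c("auto", "json", "csv"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) return(ext)
  stop(sprintf("cannot infer landmark file format from extension '.%s'; pass format=", ext),
       call. = FALSE)
}

#' Read landmark sets from a JSON or CSV file
#'
#' JSON schema: a top-level array of objects
#' `{"photo_id", "image_width", "image_height", "landmarks": {"<name>": [x, y], ...}}`.
#' CSV schema: one row per photograph with columns `photo_id`, `image_width`,
#' `image_height`, then `<name>_x`, `<name>_y` for the nine landmark names.
#' Every record is validated on read (see [validate_landmarks()]); a missing
#' landmark key or a non-numeric coordinate is an error naming the photo and
#' key.
#'
#' @param path File to read.
#' @param format `"json"`, `"csv"`, or `"auto"` (default; by extension).
#' @return List of `back_landmarks`, one per record.
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path, format = "auto") {
  records <- parse_landmark_records(path, format)
  errs <- vapply(records, function(r) {
    if (inherits(r, "back_landmarks")) NA_character_ else r$error
  }, character(1))
  bad <- which(!is.na(errs))
  if (length(bad) > 0L) {
    stop(paste(errs[bad], collapse = "\n"), call. = FALSE)
  }
  records
}

#' Parse landmark records, collecting per-record failures
#'
#' Like [read_landmarks()] but never fails on an invalid record: each element
#' of the returned list is either a validated `back_landmarks` or a list
#' `list(photo_id =, error =)` describing the failure. Used by the batch
#' command-line path so one bad annotation does not abort a run.
#'
#' @inheritParams read_landmarks
#' @return List of `back_landmarks` or error records.
#' @export
parse_landmark_records <- function(path, format = "auto") {
  if (!file.exists(path)) {
    stop(sprintf("landmark file not found: '%s'", path), call. = FALSE)
  }
  format <- .guess_format(path, format)
  raw <- if (format == "json") .parse_landmarks_json(path) else .parse_landmarks_csv(path)
  lapply(raw, function(rec) {
    tryCatch(
      back_landmarks(rec$photo_id, rec$points,
                     image_width = rec$image_width,
                     image_height = rec$image_height),
      error = function(e) list(photo_id = as.character(rec$photo_id),
                               error = conditionMessage(e))
    )
  })
}

.parse_landmarks_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(seq_along(doc), function(i) {
    rec <- doc[[i]]
    id <- rec$photo_id
    if (is.null(id)) id <- sprintf("<record %d>", i)
    pts <- rec$landmarks
    if (is.null(pts)) pts <- list()
    pts <- lapply(pts, function(p) {
      xy <- suppressWarnings(as.numeric(unlist(p)))
      if (length(xy) != 2L || any(is.na(xy))) {
        stop(sprintf("photo '%s': non-numeric coordinate in record %d of '%s'",
                     id, i, path), call. = FALSE)
      }
      xy
    })
    list(
      photo_id = id,
      image_width = if (is.null(rec$image_width)) NA else rec$image_width,
      image_height = if (is.null(rec$image_height)) NA else rec$image_height,
      points = pts
    )
  })
}

.parse_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"photo_id" %in% names(df)) {
    stop(sprintf("landmark CSV '%s' lacks the required 'photo_id' column", path),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    id <- as.character(row$photo_id)
    pts <- list()
    for (nm in LANDMARK_NAMES) {
      cx <- paste0(nm, "_x")
      cy <- paste0(nm, "_y")
      if (cx %in% names(df) && cy %in% names(df)) {
        x <- suppressWarnings(as.numeric(row[[cx]]))
        y <- suppressWarnings(as.numeric(row[[cy]]))
        if (is.na(x) || is.na(y)) {
          stop(sprintf("photo '%s': non-numeric coordinate for '%s' at row %d of '%s'",
                       id, nm, i, path), call. = FALSE)
        }
        pts[[nm]] <- c(x, y)
      }
    }
    w <- if ("image_width" %in% names(df)) suppressWarnings(as.numeric(row$image_width)) else NA
    h <- if ("image_height" %in% names(df)) suppressWarnings(as.numeric(row$image_height)) else NA
    list(photo_id = id, image_width = w, image_height = h, points = pts)
  })
}

#' Write landmark sets to a JSON or CSV file
#'
#' Inverse of [read_landmarks()]: coordinates are serialised with 17
#' significant digits so the round trip is exact at double precision. An empty
#' record list produces a valid file with zero records.
#'
#' @param records List of `back_landmarks`.
#' @param path Output file.
#' @param format `"json"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(records, path, format = "auto") {
  format <- .guess_format(path, format)
  if (format == "json") {
    payload <- lapply(records, function(r) {
      list(
        photo_id = r$photo_id,
        image_width = if (is.finite(r$image_width)) r$image_width else NULL,
        image_height = if (is.finite(r$image_height)) r$image_height else NULL,
        landmarks = lapply(r$landmarks, unname)
      )
    })
    # I(17) = 17 significant digits: exact double-precision round trip
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  } else {
    header <- c("photo_id", "image_width", "image_height",
                as.vector(rbind(paste0(LANDMARK_NAMES, "_x"),
                                paste0(LANDMARK_NAMES, "_y"))))
    rows <- vapply(records, function(r) {
      coords <- unlist(lapply(r$landmarks[LANDMARK_NAMES], function(p) {
        sprintf("%.17g", c(p[["x"]], p[["y"]]))
      }))
      dims <- vapply(c(r$image_width, r$image_height), function(d) {
        if (is.finite(d)) sprintf("%.17g", d) else ""
      }, character(1))
      paste(c(r$photo_id, dims, coords), collapse = ",")
    }, character(1))
    writeLines(c(paste(header, collapse = ","), rows), path)
  }
  invisible(path)
}
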