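#' Construct a frame-level recording
#'
#' A recording is one subject x condition stream of per-frame emotion
#' intensities, the unit every downstream stage consumes. Intensities live in
#' \[0, 1\]; timestamps are seconds from the recording start, strictly
#' increasing and spaced at 1/fps.
#'
#' @param subject_id Opaque subject label.
#' @param condition `"inclusion"` or `"exclusion"`.
#' @param fps Frames per second, 30 or 60.
#' @param time Numeric vector of frame timestamps (seconds).
#' @param intensities Numeric matrix, frames x 7 emotions, columns named as
#'   [emotion_levels()].
#' @param neutral Optional numeric vector of per-frame neutral intensities.
#' @param validate Check invariants (default TRUE).
#' @param duration_window Admissible total duration in seconds; recordings
#'   outside it are rejected when `validate = TRUE`. Set to NULL to skip.
#' @return An object of class `facer_recording`.
#' @export
new_recording <- function(subject_id, condition, fps, time, intensities,
                          neutral = NULL, validate = TRUE,
                          duration_window = c(105, 160)) {
  condition <- match.arg(condition, c("inclusion", "exclusion"))
  intensities <- as.matrix(intensities)
  if (!identical(colnames(intensities), EMOTIONS)) {
    if (all(EMOTIONS %in% colnames(intensities))) {
      intensities <- intensities[, EMOTIONS, drop = FALSE]
    } else {
      stop("intensity columns must be exactly the 7 canonical emotions")
    }
  }
  rec <- structure(
    list(subject_id = as.character(subject_id), condition = condition,
         fps = as.integer(fps), time = as.numeric(time),
         intensities = intensities, neutral = neutral),
    class = "facer_recording"
  )
  if (validate) validate_recording(rec, duration_window = duration_window)
  rec
}

#' Validate recording invariants
#'
#' @param rec A `facer_recording`.
#' @param duration_window Admissible duration in seconds, or NULL to skip.
#' @return `rec`, invisibly; stops on violation.
#' @export
validate_recording <- function(rec, duration_window = c(105, 160)) {
  if (!rec$fps %in% c(30L, 60L)) stop("fps must be 30 or 60")
  n <- length(rec$time)
  if (nrow(rec$intensities) != n) stop("time/intensity length mismatch")
  if (n > 1) {
    dt <- diff(rec$time)
    if (any(dt <= 0)) stop("frame timestamps must be strictly increasing")
    if (any(abs(dt - 1 / rec$fps) > 0.25 / rec$fps)) {
      stop("frame spacing inconsistent with fps = ", rec$fps)
    }
  }
  bad <- which(rec$intensities < 0 | rec$intensities > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("intensity outside [0,1] at row %d (%s)",
                 bad[1, 1], colnames(rec$intensities)[bad[1, 2]]))
  }
  if (!is.null(rec$neutral) && any(rec$neutral < 0 | rec$neutral > 1)) {
    stop("neutral intensity outside [0,1] at row ",
         which(rec$neutral < 0 | rec$neutral > 1)[1])
  }
  if (!is.null(duration_window)) {
    dur <- recording_duration(rec)
    if (dur < duration_window[1] || dur > duration_window[2]) {
      stop(sprintf("duration %.1f s outside admissible window [%g, %g]",
                   dur, duration_window[1], duration_window[2]))
    }
  }
  invisible(rec)
}

#' Recording duration in seconds
#' @param rec A `facer_recording`.
#' @return Duration (frame count / fps).
#' @export
recording_duration <- function(rec) length(rec$time) / rec$fps

#' @export
print.facer_recording <- function(x, ...) {
  cat(sprintf("<facer_recording> subject %s, %s, %d fps, %d frames (%.1f s)\n",
              x$subject_id, x$condition, x$fps, length(x$time),
              recording_duration(x)))
  invisible(x)
}

# Parse "HH:MM:SS.fff" (or "MM:SS.fff") timestamps; numeric strings pass
# through unchanged.
parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  if (!any(grepl(":", x, fixed = TRUE))) {
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out)) stop("unparseable timestamp values")
    return(out)
  }
  vapply(strsplit(x, ":", fixed = TRUE), function(parts) {
    parts <- as.numeric(parts)
    if (anyNA(parts)) stop("unparseable timestamp values")
    sum(parts * 60^rev(seq_along(parts) - 1))
  }, numeric(1))
}

#' Read a FaceReader-style detailed frame log
#'
#' Reads a delimited text export (comma or tab, autodetected) with a header
#' row naming a timestamp column plus the seven emotions and, optionally,
#' Neutral. Column matching is case-insensitive; unknown extra columns are
#' ignored with a warning. Timestamps may be plain seconds or
#' `HH:MM:SS.fff`.
#'
#' @param path File path.
#' @param subject_id,condition,fps Recording metadata.
#' @param duration_window Passed to [validate_recording()].
#' @return A `facer_recording`.
#' @export
read_recording <- function(path, subject_id, condition, fps,
                           duration_window = c(105, 160)) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  nm <- tolower(trimws(names(df)))
  time_col <- which(nm %in% c("time", "timestamp", "video time", "time_s"))
  if (length(time_col) == 0) stop("format error: missing timestamp column")
  emo_idx <- match(EMOTIONS, nm)
  if (anyNA(emo_idx)) {
    stop("format error: missing required column(s): ",
         paste(EMOTIONS[is.na(emo_idx)], collapse = ", "))
  }
  neutral_idx <- match("neutral", nm)
  known <- c(time_col[1], emo_idx, neutral_idx)
  extra <- setdiff(seq_along(nm), known[!is.na(known)])
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ",
            paste(names(df)[extra], collapse = ", "))
  }
  intensities <- as.matrix(df[, emo_idx, drop = FALSE])
  colnames(intensities) <- EMOTIONS
  bad <- which(intensities < 0 | intensities > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("validation error: %s = %.4g outside [0,1] in row %d",
                 colnames(intensities)[bad[1, 2]],
                 intensities[bad[1, 1], bad[1, 2]], bad[1, 1]))
  }
  neutral <- if (!is.na(neutral_idx)) as.numeric(df[[neutral_idx]]) else NULL
  new_recording(subject_id, condition, fps,
                time = parse_timestamps(df[[time_col[1]]]),
                intensities = intensities, neutral = neutral,
                duration_window = duration_window)
}

#' Write a recording as a CSV frame log
#'
#' Inverse of [read_recording()]: emits time + the seven emotion columns
#' (+ Neutral when present), one frame per row.
#'
#' @param rec A `facer_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time = rec$time, check.names = FALSE)
  for (e in EMOTIONS) df[[e]] <- rec$intensities[, e]
  if (!is.null(rec$neutral)) df[["neutral"]] <- rec$neutral
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Discard the lead-in of a recording
#'
#' Removes the initial seconds of a recording (the period before the game is
#' running; 14 s by default) and re-zeroes the timestamps so that analysis
#' second 1 starts at the first retained frame.
#'
#' @param rec A `facer_recording`.
#' @param lead_s Seconds to discard from the start (default 14).
#' @return The trimmed `facer_recording`.
#' @export
trim_lead <- function(rec, lead_s = 14) {
  if (lead_s < 0) stop("lead_s must be non-negative")
  if (lead_s == 0) return(rec)
  if (recording_duration(rec) <= lead_s) {
    stop("empty-recording error: duration <= lead_s")
  }
  keep <- rec$time >= lead_s - 1e-9
  new_recording(rec$subject_id, rec$condition, rec$fps,
                time = rec$time[keep] - rec$time[keep][1],
                intensities = rec$intensities[keep, , drop = FALSE],
                neutral = rec$neutral[keep],
                validate = FALSE)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `condition`, `fps`,
#' `path` (paths relative to the manifest's directory). Returns the list of
#' recordings it names.
#'
#' @param path Manifest CSV path.
#' @param duration_window Passed to [read_recording()].
#' @return List of `facer_recording` objects.
#' @export
read_cohort_manifest <- function(path, duration_window = c(105, 160)) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "condition", "fps", "path")
  if (!all(req %in% names(man))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_recording(p, man$subject_id[i], man$condition[i], man$fps[i],
                   duration_window = duration_window)
  })
}
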