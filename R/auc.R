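#' Trapezium-rule area under a series
#'
#' @param y Numeric series (>= 2 points).
#' @param dx Abscissa step between consecutive points (default 1 second).
#' @return `dx * sum((y_i + y_{i+1}) / 2)`.
#' @export
trapezium_auc <- function(y, dx = 1) {
  n <- length(y)
  if (n < 2) stop("series must have at least 2 points")
  dx * sum((y[-1] + y[-n]) / 2)
}

#' Standardize an AUC onto a common frame axis
#'
#' AUCs are computed on the per-second intensity series; multiplying by a
#' reference frame rate expresses every subject's AUC on the same
#' frame-count axis, so recordings captured at 30 and 60 fps are directly
#' comparable (the per-second series already absorbs the native frame rate).
#'
#' @param raw_auc AUC on the per-second axis.
#' @param fps Native frame rate of the recording (30 or 60); kept for the
#'   record, the standardized value does not depend on it.
#' @param ref_fps Reference frame rate (default 30).
#' @return Standardized AUC in frame x intensity units.
#' @export
standardize_auc <- function(raw_auc, fps = 30, ref_fps = 30) {
  if (!all(fps %in% c(30, 60))) stop("fps must be 30 or 60")
  raw_auc * ref_fps
}

#' Per-segment and total AUCs of one recording
#'
#' One trapezium AUC per emotion for each temporal segment and for the full
#' series, standardized onto the reference frame axis. A segment covered by
#' fewer than 2 seconds of data is NA; a partial tail (recordings shorter
#' than the timeline) is integrated as far as data reach.
#'
#' @param series A `second_series` (from [per_second_means()]).
#' @param timeline An [analysis_timeline()].
#' @param standardize Multiply onto the reference frame axis (default TRUE).
#' @param ref_fps Reference frame rate for [standardize_auc()].
#' @return Data frame of AUC records: subject_id, condition, scope (one of
#'   "total", "segment1".."segment3"), emotion, auc.
#' @export
segment_aucs <- function(series, timeline = analysis_timeline(),
                         standardize = TRUE, ref_fps = 30) {
  m <- unclass(series)
  n_sec <- nrow(m)
  fps <- attr(series, "fps")
  scale <- if (standardize) ref_fps else 1
  scopes <- c(list(total = seq_len(n_sec)),
              setNames(lapply(seq_len(nrow(timeline$segments)), function(i) {
                s <- timeline$segments[i, ]
                secs <- s$start:min(s$end, n_sec)
                if (s$start > n_sec) integer(0) else secs
              }), paste0("segment", timeline$segments$segment)))
  rows <- lapply(names(scopes), function(sc) {
    secs <- scopes[[sc]]
    auc <- if (length(secs) < 2) {
      rep(NA_real_, length(EMOTIONS))
    } else {
      apply(m[secs, , drop = FALSE], 2, trapezium_auc, dx = 1) * scale
    }
    data.frame(subject_id = attr(series, "subject_id") %||% NA_character_,
               condition = attr(series, "condition") %||% NA_character_,
               scope = sc, emotion = EMOTIONS, auc = unname(auc))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' AUCs for a whole cohort of recordings
#'
#' Convenience wrapper: per-second means then [segment_aucs()] for each
#' recording, bound into one long table.
#'
#' @param recordings List of trimmed `facer_recording` objects.
#' @param timeline An [analysis_timeline()].
#' @param ref_fps Reference frame rate.
#' @return Long data frame of AUC records.
#' @export
cohort_aucs <- function(recordings, timeline = analysis_timeline(),
                        ref_fps = 30) {
  do.call(rbind, lapply(recordings, function(rec) {
    segment_aucs(per_second_means(rec), timeline, ref_fps = ref_fps)
  }))
}

#' Masked-emotion AUCs
#'
#' Masking (smiling over a negative emotion) is quantified by adding the
#' happiness AUC to each other emotion's AUC, within subject, condition and
#' scope.
#'
#' @param records AUC record data frame (from [segment_aucs()] or
#'   [cohort_aucs()]).
#' @return Data frame: subject_id, condition, scope, emotion (six
#'   non-happiness emotions), auc, auc_happiness, masked (= auc +
#'   auc_happiness).
#' @export
masked_auc <- function(records) {
  hap <- records[records$emotion == "happiness",
                 c("subject_id", "condition", "scope", "auc")]
  names(hap)[4] <- "auc_happiness"
  oth <- records[records$emotion != "happiness", ]
  out <- merge(oth, hap, by = c("subject_id", "condition", "scope"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$auc_happiness) && !anyNA(out$auc)) {
    stop("missing happiness AUC for some subject/condition/scope")
  }
  out$masked <- out$auc + out$auc_happiness
  out[order(out$subject_id, out$condition, out$scope), ]
}

#' Per-subject AUC composition shares
#'
#' For each subject, condition and scope, the share of each emotion's AUC in
#' the seven-emotion total (the pie-chart decomposition). Shares sum to 1
#' whenever the total AUC is positive; an all-zero scope is flagged and its
#' shares are NA.
#'
#' @param records AUC record data frame.
#' @return Data frame: subject_id, condition, scope, emotion, share,
#'   degenerate flag.
#' @export
auc_proportions <- function(records) {
  key <- interaction(records$subject_id, records$condition, records$scope,
                     drop = TRUE)
  totals <- tapply(records$auc, key, sum)
  tot <- as.numeric(totals[as.character(key)])
  share <- ifelse(tot > 0, records$auc / tot, NA_real_)
  data.frame(subject_id = records$subject_id, condition = records$condition,
             scope = records$scope, emotion = records$emotion,
             share = share, degenerate = !(tot > 0))
}
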