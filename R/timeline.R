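#' Canonical primary-emotion labels
#'
#' The seven primary facial-expression categories scored continuously in
#' \[0, 1\] by automated facial coding, in the column order of FaceReader
#' exports. This order is also the deterministic tie-break used whenever a
#' dominant emotion must be resolved among equal scores.
#'
#' @return Character vector of length 7.
#' @export
emotion_levels <- function() {
  c("happiness", "sadness", "anger", "surprise", "fear", "disgust", "contempt")
}

# internal shorthand
EMOTIONS <- c("happiness", "sadness", "anger", "surprise", "fear", "disgust",
              "contempt")

#' Analysis timeline: segments and 15-second intervals
#'
#' The analysed game time (after the 14 s lead-in is discarded) is indexed by
#' 1-based whole seconds and divided into three temporal segments which are in
#' turn split into ten intervals. Interval 3 spans 14 s (seconds 31-44),
#' interval 5 spans 16 s (60-75) and interval 10 spans 10 s (136-145); all
#' others span 15 s.
#'
#' @param n_seconds Total analysed seconds covered by the timeline (default
#'   145).
#' @return An object of class `cyberface_timeline`: a list with data frames
#'   `segments` (segment, start, end) and `intervals` (interval, start, end,
#'   segment), boundaries in analysis-seconds (closed intervals).
#' @export
analysis_timeline <- function(n_seconds = 145) {
  segments <- data.frame(
    segment = 1:3,
    start   = c(1, 60, 106),
    end     = c(59, 105, 145)
  )
  intervals <- data.frame(
    interval = 1:10,
    start    = c(1, 16, 31, 45, 60, 76, 91, 106, 121, 136),
    end      = c(15, 30, 44, 59, 75, 90, 105, 120, 135, 145),
    segment  = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  )
  segments$end[3] <- max(segments$end[3], n_seconds)
  structure(
    list(segments = segments, intervals = intervals, n_seconds = n_seconds),
    class = "cyberface_timeline"
  )
}

#' @export
print.cyberface_timeline <- function(x, ...) {
  cat("Analysis timeline over", x$n_seconds, "seconds\n")
  cat("Segments:\n")
  print(x$segments, row.names = FALSE)
  cat("Intervals:\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Segment label of an analysis second
#'
#' @param second Vector of 1-based analysis seconds.
#' @param timeline A [analysis_timeline()] object.
#' @return Integer vector of segment numbers (NA outside the timeline;
#'   seconds beyond the last boundary fall into segment 3).
#' @export
segment_of_second <- function(second, timeline = analysis_timeline()) {
  seg <- rep(NA_integer_, length(second))
  for (i in seq_len(nrow(timeline$segments))) {
    s <- timeline$segments[i, ]
    seg[second >= s$start & second <= s$end] <- s$segment
  }
  seg
}
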