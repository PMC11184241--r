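# Shared fixture builders: everything is generated in code at test time.

emotions <- cyberface::emotion_levels()

# A recording with per-emotion intensities given as constants or per-frame
# vectors; bypasses the duration-window check so short test streams are fine.
make_recording <- function(values, fps = 30, duration = 3,
                           subject_id = "T1", condition = "inclusion",
                           neutral = NULL) {
  n <- duration * fps
  X <- sapply(emotions, function(e) {
    v <- if (e %in% names(values)) values[[e]] else 0
    rep_len(v, n)
  })
  if (!is.null(neutral)) neutral <- rep_len(neutral, n)
  new_recording(subject_id, condition, fps, time = (seq_len(n) - 1) / fps,
                intensities = X, neutral = neutral, validate = FALSE)
}

# A small, fast cohort spec (fewer subjects, shorter recordings) used where
# only structure, not the study conditions, is exercised.
small_spec <- function(seed = 1, duration_s = c(44, 50), ...) {
  cohort_spec(n_subjects = 4, fps_assignment = c(30L, 30L, 30L, 60L),
              duration_s = duration_s, seed = seed, ...)
}

# A group pattern from random dominant labels: n_subjects iid uniform labels
# per second. Returns percentages (rows sum to 100).
random_pattern <- function(n_seconds, n_subjects = 14) {
  counts <- stats::rmultinom(n_seconds, n_subjects, rep(1 / 7, 7))
  m <- t(counts) / n_subjects * 100
  colnames(m) <- emotions
  structure(m, class = "group_pattern", n_subjects = rep(n_subjects,
                                                         n_seconds))
}
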