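#' Continuous-calibration of an expression intensity
#'
#' FaceReader's continuous calibration adapts intensity scores to a person's
#' baseline face when no neutral reference frame was captured. The corrected
#' intensity of the current frame is
#' \deqn{\max\!\left(0, \frac{l_a - l_m}{1 - l_a}\right)}
#' where `l_a` is the raw intensity in the current frame and `l_m` the mean
#' raw intensity over all frames before it. Whenever `l_a <= l_m` the
#' corrected intensity is 0.
#'
#' @param l_a Raw intensity in the current frame, in \[0, 1).
#' @param l_m Running mean intensity over previous frames, in \[0, 1\].
#' @return Calibrated intensity (vectorized), always >= 0. Values are not
#'   clamped above here; [apply_continuous_calibration()] clamps to 1.
#' @export
calibrate_intensity <- function(l_a, l_m) {
  if (any(l_a < 0 | l_a > 1) || any(l_m < 0 | l_m > 1)) {
    stop("inputs must lie in [0,1]")
  }
  if (any(l_a == 1)) stop("singular input: l_a = 1 (denominator zero)")
  pmax(0, (l_a - l_m) / (1 - l_a))
}

#' Continuous-calibration of the neutral intensity
#'
#' The corrected neutral intensity is \eqn{(N_a + (1 - l_{max,m})) / 2},
#' where `N_a` is the raw neutral intensity of the current frame and
#' `l_max_m` the maximum running-mean intensity across the seven emotions
#' over all frames before it. The result is guaranteed to lie in \[0, 1\].
#'
#' @param N_a Raw neutral intensity, in \[0, 1\].
#' @param l_max_m Maximum running-mean emotion intensity, in \[0, 1\].
#' @return Calibrated neutral intensity (vectorized).
#' @export
calibrate_neutral <- function(N_a, l_max_m) {
  if (any(N_a < 0 | N_a > 1) || any(l_max_m < 0 | l_max_m > 1)) {
    stop("validation error: inputs must lie in [0,1]")
  }
  (N_a + (1 - l_max_m)) / 2
}

#' Apply continuous calibration to a whole recording
#'
#' Replays the running-mean correction over a frame stream: frame i's emotion
#' intensities are recalibrated with [calibrate_intensity()] using the
#' per-emotion mean over frames 1..i-1, and the neutral channel with
#' [calibrate_neutral()] using the maximum of those running means. Frame 1
#' uses running means of 0 (no prior evidence), so its raw intensities pass
#' through.
#'
#' Raw intensities equal to 1 are treated as 1 - 1e-9 to avoid the singular
#' denominator; calibrated values above 1 are clamped to 1. Both events are
#' counted in the `calibration_diagnostics` attribute of the result.
#'
#' @param rec A `facer_recording`.
#' @return The calibrated `facer_recording`, with attribute
#'   `calibration_diagnostics` = list(n_singular, n_clamped).
#' @export
apply_continuous_calibration <- function(rec) {
  X <- rec$intensities
  n <- nrow(X)
  n_singular <- sum(X == 1)
  if (n_singular > 0) {
    message(n_singular, " raw intensities equal to 1 treated as 1 - 1e-9")
    X[X == 1] <- 1 - 1e-9
  }
  # per-emotion mean over frames strictly before each frame; row 1 gets 0
  prior_mean <- apply(X, 2, function(col) {
    c(0, cumsum(col)[-n] / seq_len(n - 1))
  })
  if (n == 1) prior_mean <- matrix(0, 1, ncol(X), dimnames = dimnames(X))
  cal <- (X - prior_mean) / (1 - X)
  cal[cal < 0] <- 0
  n_clamped <- sum(cal > 1)
  if (n_clamped > 0) {
    message(n_clamped, " calibrated intensities above 1 clamped to 1")
    cal[cal > 1] <- 1
  }
  neutral <- rec$neutral
  if (!is.null(neutral)) {
    l_max_m <- apply(prior_mean, 1, max)
    neutral <- calibrate_neutral(neutral, pmin(l_max_m, 1))
  }
  out <- new_recording(rec$subject_id, rec$condition, rec$fps, rec$time,
                       cal, neutral, validate = FALSE)
  attr(out, "calibration_diagnostics") <-
    list(n_singular = n_singular, n_clamped = n_clamped)
  out
}
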