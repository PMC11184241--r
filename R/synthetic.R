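#' Specify an injected emotion effect
#'
#' Effects perturb the latent (logit-scale) intensity of one emotion under
#' one condition over a range of temporal segments, either as a constant
#' shift or as a linear ramp from 0 up to `magnitude` across the covered
#' span. They encode the structures the analysis is meant to detect, e.g. an
#' anger trajectory that rises during inclusion and falls during exclusion,
#' or a late-exclusion rise in happiness and surprise.
#'
#' @param emotion One of [emotion_levels()].
#' @param condition `"inclusion"` or `"exclusion"`.
#' @param segments Integer subset of 1:3 (contiguous) the effect covers.
#' @param shape `"constant"` or `"ramp"`.
#' @param magnitude Latent-scale (logit) effect size at full strength.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(emotion, condition, segments = 1:3,
                        shape = c("constant", "ramp"), magnitude) {
  emotion <- match.arg(emotion, EMOTIONS)
  condition <- match.arg(condition, c("inclusion", "exclusion"))
  shape <- match.arg(shape)
  if (!all(segments %in% 1:3)) stop("segments must lie in 1:3")
  structure(list(emotion = emotion, condition = condition,
                 segments = sort(unique(segments)), shape = shape,
                 magnitude = magnitude),
            class = "effect_spec")
}

#' Specify a synthetic cohort
#'
#' Collects every parameter of the synthetic-data generator: cohort size and
#' frame-rate assignment, recording durations, the latent (logit-scale)
#' baseline intensity per emotion, injected [effect_spec()]s, the temporal
#' noise process (per-second AR(1) autocorrelation and stationary SD, plus a
#' between-subject latent intercept SD shared across conditions), the
#' post-game need-threat (NTS) score model, and the Gaussian-copula Spearman
#' targets for the clinical scales.
#'
#' @param n_subjects Number of subjects (default 14).
#' @param fps_assignment Integer vector of frame rates per subject (default
#'   12 subjects at 30 fps, 2 at 60 fps).
#' @param duration_s Range (min, max) of total recording duration in whole
#'   seconds, including the lead-in (default 129-159 s).
#' @param lead_s Discarded lead-in seconds (default 14).
#' @param baseline Named latent mean per emotion (logit scale).
#' @param effects List of [effect_spec()] objects.
#' @param ar_coefficient Per-second AR(1) autocorrelation of the latent
#'   noise, in \[0, 1).
#' @param noise_sd Stationary SD of the latent noise.
#' @param subject_sd SD of the per-subject, per-emotion latent intercept
#'   (shared across conditions; this is what induces cross-condition
#'   correlation of AUCs).
#' @param nts List with `means` (inclusion, exclusion), `sd`, `cor`
#'   (cross-condition correlation) and `range`.
#' @param scale_correlations 5 x 5 Spearman target matrix among SCID-II,
#'   BIS-15, BEST, DERS-E and NTS, symmetric with unit diagonal.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14,
                        fps_assignment = c(rep(30L, 12), rep(60L, 2)),
                        duration_s = c(129, 159),
                        lead_s = 14,
                        baseline = c(happiness = -3.5, sadness = -2.7,
                                     anger = -3.4, surprise = -4.0,
                                     fear = -4.6, disgust = -4.9,
                                     contempt = -3.2),
                        effects = list(),
                        ar_coefficient = 0.7,
                        noise_sd = 1.0,
                        subject_sd = 0.3,
                        nts = list(means = c(inclusion = 78.50,
                                             exclusion = 110.57),
                                   sd = 29, cor = 0.69, range = c(14, 140)),
                        scale_correlations = default_scale_correlations(),
                        seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (length(fps_assignment) != n_subjects) {
    fps_assignment <- rep_len(fps_assignment, n_subjects)
  }
  if (!all(fps_assignment %in% c(30, 60))) stop("fps must be 30 or 60")
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("ar_coefficient must lie in [0, 1)")
  }
  if (!isTRUE(all.equal(scale_correlations, t(scale_correlations))) ||
      any(diag(scale_correlations) != 1)) {
    stop("scale_correlations must be symmetric with unit diagonal")
  }
  if (!identical(sort(names(baseline)), sort(EMOTIONS))) {
    stop("baseline must name all 7 emotions")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         fps_assignment = as.integer(fps_assignment),
         duration_s = duration_s, lead_s = lead_s,
         baseline = baseline[EMOTIONS], effects = effects,
         ar_coefficient = ar_coefficient, noise_sd = noise_sd,
         subject_sd = subject_sd, nts = nts,
         scale_correlations = scale_correlations, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects, %d effects, seed %d\n",
              x$n_subjects, length(x$effects), x$seed))
  invisible(x)
}

#' Spearman targets among the clinical scales
#'
#' The default correlation structure of the clinical instruments (SCID-II,
#' BIS-15, BEST, DERS-E, NTS) reproduced by the score generator, e.g.
#' rho(SCID-II, DERS-E) = 0.68.
#'
#' @return 5 x 5 symmetric Spearman matrix.
#' @export
default_scale_correlations <- function() {
  nm <- c("scid_ii", "bis15", "best", "ders_e", "nts")
  m <- matrix(c(
    1.00, 0.37, 0.65, 0.68, 0.14,
    0.37, 1.00, 0.16, 0.23, -0.02,
    0.65, 0.16, 1.00, 0.32, -0.08,
    0.68, 0.23, 0.32, 1.00, 0.12,
    0.14, -0.02, -0.08, 0.12, 1.00
  ), 5, 5, dimnames = list(nm, nm))
  m
}

#' Default cohort specification
#'
#' The calibrated defaults of the generator: 14 subjects (12 at 30 fps, 2 at
#' 60 fps), two ~2-2.5 minute recordings each, latent baselines that make
#' sadness the most frequent dominant emotion with contempt and anger next,
#' an anger condition x segment interaction (rising during inclusion,
#' falling during exclusion), a late-exclusion rise in happiness and
#' surprise, an NTS inclusion/exclusion shift of ~32 points, and the
#' clinical-scale Spearman structure of [default_scale_correlations()].
#'
#' @param seed Integer seed (default 1).
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    effects = list(
      effect_spec("anger", "inclusion", 1:3, "ramp", 0.8),
      effect_spec("anger", "exclusion", 1:3, "ramp", -1.0),
      effect_spec("happiness", "exclusion", 2:3, "ramp", 1.2),
      effect_spec("surprise", "exclusion", 2:3, "ramp", 1.0)
    ),
    seed = seed
  )
}

# Latent effect contribution of spec effects for one emotion/condition at
# each analysis second 1..n_sec. Segment 3 is extended to cover n_sec.
effect_profile <- function(effects, emotion, condition, n_sec,
                           timeline = analysis_timeline()) {
  prof <- numeric(n_sec)
  segs <- timeline$segments
  segs$end[3] <- max(segs$end[3], n_sec)
  for (ef in effects) {
    if (ef$emotion != emotion || ef$condition != condition) next
    span <- c(segs$start[min(ef$segments)], segs$end[max(ef$segments)])
    secs <- span[1]:min(span[2], n_sec)
    if (length(secs) == 0 || secs[1] > n_sec) next
    prof[secs] <- prof[secs] + if (ef$shape == "constant") {
      ef$magnitude
    } else {
      ef$magnitude * (secs - span[1] + 1) / (span[2] - span[1] + 1)
    }
  }
  prof
}

# One synthetic frame-level recording: latent = baseline + subject intercept
# + effect profile + AR(1) noise, mapped through the logistic link.
simulate_recording <- function(subject_id, condition, fps, duration,
                               lead_s, baseline, subj_eff, effects,
                               ar, noise_sd) {
  n <- duration * fps
  time <- (seq_len(n) - 1) / fps
  asec <- floor(time) + 1L - lead_s          # analysis second; <= 0 in lead
  n_sec <- duration - lead_s
  phi <- ar^(1 / fps)                        # per-frame AR coefficient
  innov_sd <- noise_sd * sqrt(1 - phi^2)
  X <- matrix(0, n, length(EMOTIONS), dimnames = list(NULL, EMOTIONS))
  for (e in EMOTIONS) {
    prof <- effect_profile(effects, e, condition, n_sec)
    mu <- baseline[[e]] + subj_eff[[e]] +
      ifelse(asec >= 1, prof[pmax(asec, 1)], 0)
    z <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                                  method = "recursive",
                                  init = rnorm(1, 0, noise_sd)))
    X[, e] <- plogis(mu + z)
  }
  neutral <- pmax(0, 1 - apply(X, 1, max))
  new_recording(subject_id, condition, fps, time, X, neutral,
                validate = FALSE)
}

#' Generate a synthetic cohort
#'
#' Produces one recording per subject per condition plus clinical scores,
#' deterministically given the seed. Per-frame emotion intensities follow a
#' latent logistic AR(1) model: logit-scale latent value = baseline +
#' subject intercept + injected effect + AR(1) noise, pushed through the
#' logistic link into \[0, 1\] (intensities are not constrained to sum to 1,
#' matching automated facial-coding outputs). The AR coefficient is
#' parameterized per second, so the process is invariant to the native frame
#' rate. The neutral channel is 1 minus the frame's maximum emotion
#' intensity.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed override (default `spec$seed`).
#' @return List of class `synthetic_cohort`: `recordings` (list of
#'   `facer_recording`, untrimmed — they include the lead-in), `scores`
#'   (data frame from [generate_clinical_scores()]), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  withr::with_seed(seed, {
    subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
    # per-subject, per-emotion latent intercept shared across conditions
    subj_eff <- matrix(rnorm(spec$n_subjects * 7, 0, spec$subject_sd),
                       spec$n_subjects, 7, dimnames = list(subjects, EMOTIONS))
    recordings <- list()
    for (i in seq_len(spec$n_subjects)) {
      for (cond in c("inclusion", "exclusion")) {
        duration <- spec$duration_s[1] +
          sample.int(spec$duration_s[2] - spec$duration_s[1] + 1L, 1) - 1L
        recordings[[length(recordings) + 1]] <- simulate_recording(
          subjects[i], cond, spec$fps_assignment[i], duration, spec$lead_s,
          spec$baseline, as.list(subj_eff[i, ]), spec$effects,
          spec$ar_coefficient, spec$noise_sd
        )
      }
    }
    scores <- generate_clinical_scores(spec, n = spec$n_subjects, seed = NULL)
    scores$subject_id <- subjects
  })
  structure(list(recordings = recordings, scores = scores, spec = spec,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d recordings, %d subjects, seed %d\n",
              length(x$recordings), nrow(x$scores), x$seed))
  invisible(x)
}

# Quantile of a normal censored (winsorized) to [lo, hi]: monotone in u, so
# Spearman structure from the copula is preserved; mass accumulates at the
# scale bounds (ceiling/floor effects).
q_censnorm <- function(u, mean, sd, lo, hi) {
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

#' Generate clinical-scale scores
#'
#' Draws per-subject scores for SCID-II, BIS-15 (+ cognitive, motor and
#' non-planning subscales), BEST (+ A/B/C subscales), DERS-E and the
#' per-condition NTS through a Gaussian copula whose correlations are chosen
#' so the scores' Spearman matrix matches `spec$scale_correlations`
#' (Pearson = 2 sin(pi rho / 6)). Marginals are normal with the scales'
#' means/SDs, censored to each scale's range. Subscale scores share a latent
#' factor with their total (loading 0.75). The two NTS scores are a
#' correlated pair with the spec's means, SD and cross-condition
#' correlation.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of subjects (default `spec$n_subjects`; larger values are
#'   useful for calibration checks).
#' @param seed Seed, or NULL to use the current RNG state.
#' @return Data frame with subject_id, scid_ii, bis15 + subscales, best +
#'   subscales, ders_e, nts_inclusion, nts_exclusion.
#' @export
generate_clinical_scores <- function(spec, n = spec$n_subjects,
                                     seed = spec$seed) {
  gen <- function() {
    S <- spec$scale_correlations
    R <- 2 * sin(pi * S / 6)
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("spec error: correlation matrix is not positive semidefinite")
    }
    L <- chol(R + diag(1e-10, nrow(R)))
    Z <- matrix(rnorm(n * 5), n, 5) %*% L
    colnames(Z) <- colnames(S)
    U <- pnorm(Z)

    marg <- list(
      scid_ii = c(12.36, 2, 0, 30), bis15 = c(49.79, 13, 15, 60),
      best = c(44.00, 11, 12, 72), ders_e = c(81.08, 15, 28, 140)
    )
    out <- data.frame(subject_id = sprintf("S%02d", seq_len(n)))
    for (nm in names(marg)) {
      key <- if (nm == "scid_ii") "scid_ii" else nm
      m <- marg[[nm]]
      out[[nm]] <- q_censnorm(U[, key], m[1], m[2], m[3], m[4])
    }

    sub_from <- function(z_total, m) {
      z <- 0.75 * z_total + sqrt(1 - 0.75^2) * rnorm(n)
      q_censnorm(pnorm(z), m[1], m[2], m[3], m[4])
    }
    out$bis15_cognitive <- sub_from(Z[, "bis15"], c(15.93, 5, 5, 20))
    out$bis15_motor <- sub_from(Z[, "bis15"], c(13.79, 4, 5, 20))
    out$bis15_nonplanning <- sub_from(Z[, "bis15"], c(19.93, 5, 5, 20))
    out$best_a <- sub_from(Z[, "best"], c(30.00, 6, 8, 40))
    out$best_b <- sub_from(Z[, "best"], c(13.43, 4, 4, 20))
    out$best_c <- sub_from(Z[, "best"], c(12.07, 3, 3, 15))

    nts <- spec$nts
    z_inc <- Z[, "nts"]
    z_exc <- nts$cor * z_inc + sqrt(1 - nts$cor^2) * rnorm(n)
    out$nts_inclusion <- q_censnorm(pnorm(z_inc), nts$means[["inclusion"]],
                                    nts$sd, nts$range[1], nts$range[2])
    out$nts_exclusion <- q_censnorm(pnorm(z_exc), nts$means[["exclusion"]],
                                    nts$sd, nts$range[1], nts$range[2])
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a synthetic cohort to disk
#'
#' Emits one frame-log CSV per recording, a cohort manifest
#' (`manifest.csv`) readable by [read_cohort_manifest()], and the clinical
#' scores (`scores.csv`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$recordings, function(rec) {
    fname <- sprintf("%s_%s.csv", rec$subject_id, rec$condition)
    write_recording(rec, file.path(dir, fname))
    data.frame(subject_id = rec$subject_id, condition = rec$condition,
               fps = rec$fps, path = fname)
  })
  man <- do.call(rbind, rows)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
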